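---
title: "High-order brain functional networks from EEG: models and methods"
author: "hobfn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order brain functional networks from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conventional EEG functional-connectivity analysis estimates a statistical
dependence between every pair of channels — a *low-order* brain functional
network (LO-BFN) whose edges each involve exactly two channels. Interactions
that span more than two channels, for example two channel pairs whose
coupling strengths rise and fall together, are invisible to such a network.
`hobfn` implements a *high-order* network (HO-BFN) built on the
"correlation's correlation" idea: the dynamics of pairwise connectivity are
themselves correlated across pairs, and those second-level correlations form
a network whose vertices are channel pairs (or clusters of them). The
package applies this representation to two-group classification, with major
depressive disorder (MDD) versus normal controls (NC) as the motivating
task.

## The model, stage by stage

**Windowing.** A recording of $M$ samples is divided into
$H = \lfloor (M - W)/s \rfloor + 1$ overlapping windows of width $W$
advanced by step $s$ (`planWindows`). Windows are 0-based half-open
intervals so that every index computation in the tests is exact. The study
protocol fixes $W = 10000$ and $s = 1000$ samples at 250 Hz (40 s windows,
4 s step).

**Low-order connectivity.** Within window $h$, channel pair $(i, j)$ gets a
connectivity weight $C_{ij}(h)$, either

* the **phase lag index** (PLI, frequency domain):
  $C_{ij} = \lvert \frac1N \sum_n \operatorname{sign}
  (\sin(\varphi_i(t_n) - \varphi_j(t_n))) \rvert$, where $\varphi$ is the
  instantaneous phase from the Hilbert analytic signal. The sine wraps the
  phase difference; PLI is the asymmetry of the wrapped difference around
  zero, which makes it insensitive to zero-lag (volume-conduction)
  coupling. $N$ is taken to be the window width $W$.
* the **Pearson correlation** (PCC, time domain) of the raw samples.

Phase is extracted once on the full recording and windows slice the phase
series, avoiding per-window Hilbert edge artifacts. Band restriction
(theta 4–8, alpha 8–13, beta 13–40 Hz) is a hard DFT mask: forward FFT,
zero every bin outside the band, inverse FFT. The mask is an orthogonal
projection — idempotent, energy-preserving across the pass/stop split —
and has no ripple or phase distortion; its price is edge leakage for
components that are not exact DFT bins, negligible at the recording lengths
used here.

**High-order construction.** Row $r$ of the $P \times H$ series matrix
(`toSeries`) is pair $r$'s connectivity time series. The full high-order
network is the $P \times P$ Pearson correlation matrix between these rows
(`hofcFull`) — at 128 channels this has $8128^2$ entries, so it is kept
only as a small-problem reference. Production use clusters the series:
the per-pair series of all subjects are concatenated into "long vectors"
(`stackLongVectors`), giving every subject the same pair-to-cluster
assignment, and the long vectors are clustered agglomeratively
(`clusterPairs`). Each subject's cluster-mean series (`clusterMeanSeries`,
plain arithmetic mean of member rows) yield a $k \times k$ correlation
matrix (`hofcClustered`), the clustered HO-BFN. With singleton clusters the
construction reduces exactly to `hofcFull`, an identity the tests assert.

**Features and selection.** The low-order feature vector is the
window-averaged connectivity per pair (averaging removes the phase mismatch
of window dynamics across subjects; no per-window dynamic features are
exposed). The high-order feature vector is the vectorized upper triangle of
the clustered HO-BFN. Each feature block is screened by per-feature
two-sample t-tests at level $p$ and then reduced by the LASSO
$$\min_\alpha \tfrac12 \sum_l \left(I^l - \langle \bar f^{\,l},
\alpha\rangle\right)^2 + \lambda \lVert\alpha\rVert_1,$$
with labels $I^l = -1$ (MDD) / $+1$ (NC), columns standardized on training
data and the labels centered, which makes the intercept-free model
well-posed. (The source formulation prints the residual with a misplaced
sign; it is read as the standard squared-error LASSO.)

**Classification and fusion.** One linear soft-margin SVM per feature block
(low-order, high-order; per band when several bands are analyzed). The raw
decision scores $d_f(x) = \langle w_f, x\rangle + b_f$ are fused as
$\sum_f \beta_f d_f(x)$ with weights from the grid
$\{0.1, \dots, 0.9\}^F$ constrained to $\sum_f \beta_f = 1$; a negative
fused score predicts MDD, a positive one NC, and an exact tie predicts NC
(a fixed, documented rule). MDD is the positive class for sensitivity,
precision and their relatives.

**Evaluation.** Nested stratified cross-validation: outer folds estimate
generalization; for each outer fold an inner CV selects
$(k, p, \lambda, c, \beta)$ jointly by mean inner fused accuracy; the
winning configuration is refitted on the full outer training set and
evaluated once on the held-out fold; the whole procedure is repeated with
fresh partitions. Fold accuracies are averaged over folds and repeats;
the other metrics are computed from each repeat's pooled confusion counts
and averaged over repeats (for equal-size folds the two accuracy
conventions coincide, and pooling keeps ratios defined when single folds
have empty denominators).

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `W`, `s` | window width/step (samples) | 10000 / 1000 | fixed by the study protocol; 40 s / 4 s at 250 Hz |
| `k` | cluster count | grid 100–800 (full), {3, 4, 6} (desk scale) | clipped to the pair count $P$ on small problems |
| `p` | t-test level | grid 0.01–0.05 | pooled-variance Student's t by default, Welch behind a flag |
| `lambda` | LASSO penalty | grid 0.1–0.9 | on the un-normalized $\tfrac12$RSS scale |
| `c` | SVM cost | grid $2^{-4}..2^4$ | features are standardized, so c matters little for separable data |
| `beta` | fusion weights | grid $\{0.1..0.9\}^F$, sum 1 | selected on the inner CV like the other hyper-parameters |

## Design choices on genuinely open points

* **Clustering linkage and metric.** Ward linkage on Euclidean distances
  (`hclust(method = "ward.D2")`), the natural match for clusters that the
  construction represents by their means. Long vectors are not standardized
  before clustering. Distance ties would be resolved by `hclust`'s
  deterministic merge rule; the pipeline's continuous inputs do not produce
  exact ties, so determinism in practice comes from fixed input order.
* **Leakage policy.** The original all-subject protocol clusters the long
  vectors of *all* subjects — including test subjects — so that one
  assignment covers everyone. By default `hobfn` fits the clustering tree
  on training subjects only; because pairs are shared across subjects the
  assignment transfers verbatim to test subjects. The all-subject behavior
  remains available as `paperFaithful = TRUE`.
* **Selection of the fusion weight.** How $\beta$ is chosen is not
  specified in the source protocol; it is searched on the inner CV jointly
  with the other hyper-parameters. With several bands all $2B$ classifiers
  are fused over the full grid of tuples summing to 1.
* **Positive class.** Sensitivity is reported for the diagnosis task
  without naming the positive class; `hobfn` fixes MDD (label −1) as
  positive.
* **Degenerate stages.** A zero-variance series contributes correlation 0
  (with a warning) rather than NaN, keeping pipelines total. If a t-test
  screen keeps nothing, the single smallest-p feature is kept; if the LASSO
  zeroes everything, the t-test set is used (both guards keep the LASSO
  mask inside the t-test mask and are deterministic; they matter only for
  desk-scale folds).
* **Empty-mask-free audits.** Every selection stage records the subjects it
  was fitted on (`fittedOn`); the nested CV's per-fold records let tests
  assert that no stage ever saw a held-out subject.

## The synthetic-data generator

Real resting-state EEG (the motivating dataset is 128-channel, 250 Hz,
eyes-closed) cannot ship with the package, so `genEEG`/`genDataset`
generate a synthetic cohort that reproduces the *statistical structure* the
method exploits:

* channels are grouped into $G$ modules; each module has an alpha-band
  carrier (9, 10.2, 11.4 Hz for $G = 3$) and a latent coupling course — a
  standardized stationary AR(1) process ($\phi = 0.8$) over 1 s segments.
  A stationary course was chosen deliberately: a nonstationary random walk
  would make between-module sample correlations heavy-tailed (the classic
  spurious-regression effect), which neither resembles stationary
  resting-state dynamics nor yields a usable null.
* while a module's course is positive ("on"), its channels hold fixed phase
  lags spread over $(0, \pi/2]$ against the shared module oscillation, so
  within-module PLI is near 1; while "off", a channel's phase is
  independent uniform noise per sample, so its PLI against anything is near
  0. A common module phase offset is redrawn every segment; it cancels
  inside coupled pairs but decoheres the carriers across modules, so every
  uncoupled channel relation — off–off, on–off, on–on across modules — is
  statistically equivalent. This matters: it guarantees the planted group
  difference is invisible to low-order features.
* the group effect is high-order by construction: in the MDD-like group the
  courses of modules 1 and 2 are mixed,
  $z_2 \leftarrow \operatorname{std}(z_2 + \delta z_1)$, shifting their
  correlation to $\delta/\sqrt{1+\delta^2}$ ($\approx 0.89$ at the default
  $\delta = 2$) while leaving every module's marginal on-fraction — and
  hence every low-order feature — unchanged in expectation.
* `genFCSeries` plants the same structure directly at the
  connectivity-series level (module course + noise per pair) for fast
  unit-level testing of the clustering and classification stages.

**Synthetic study conditions.** Two groups of 10 subjects, 12 channels in
3 modules, 600 s at 250 Hz. The duration is deliberately longer than the
motivating 5-minute protocol: with $W = 10000$ the windowed series are
strongly autocorrelated, and $H = 141$ windows are needed for the
between-cluster correlation estimates to have useful precision; this is a
property of the estimator, not of the data source. The desk-scale CV
configuration (`synthCVConfig`) uses $k \in \{3, 4, 6\}$, $p = 0.05$,
$\lambda \in \{0.1, 0.5\}$, $c = 1$, 10 outer folds, 5 inner folds and
5 repeats — grids reduced to the ranges that matter at $P = 66$ pairs.

**What passing tests do and do not show.** The generator produces clean
narrowband oscillators with piecewise-constant coupling, additive white
noise at 10% amplitude and no 1/f background, no volume conduction, no
artifacts and no inter-subject variability in module membership. Success on
it demonstrates that the pipeline recovers the structure it is designed to
detect and that its cross-validation is honest (the $\delta = 0$ null runs
at chance); it does not demonstrate clinical performance on recorded EEG.

## Numerical and implementation notes

* PLI windows are computed from one pass of
  $\operatorname{sign}(\sin \Delta\varphi)$ over the full series with
  cumulative sums (summands are −1/0/1, so the sums are exact and identical
  to direct per-window evaluation).
* The LASSO is solved by coordinate descent (glmnet) with the penalty
  mapped to the un-normalized objective ($\lambda_{glmnet} = \lambda/n$),
  `thresh = 1e-12`; the $\lambda = 0$ limit is ordinary least squares and
  the single-column case uses the exact soft-threshold solution.
* The SVM is libsvm's C-SVC with a linear kernel; primal weights are
  recovered from the dual coefficients and the score orientation is
  normalized so positive scores predict NC.
* All randomness (fold partitions, synthetic data) derives from explicit
  integer seeds; identical configuration and seed reproduce reports and
  generated files byte-for-byte.
* Serialization uses plain CSV for matrices and JSON for reports and
  sidecar metadata; EDF input is supported by a minimal reader for
  continuous 16-bit EDF (annotation channels and signals with heterogeneous
  sampling rates are rejected).

## Command-line interface

The pipeline stages are exported R functions; a thin Rscript
(`system.file("cli", "hobfn.R", package = "hobfn")`) exposes the three
shell-level entry points — `synth` (generate a dataset), `lobfn` (write
per-subject connectivity series) and `pipeline` (the six-stage run,
writing `report.json` with the full echoed configuration). Stage-level
experimentation beyond that is expected to happen in R.

## Known limitations

* The high-order construction inherits the correlation's blindness to
  causality and sign-symmetric dependence.
* Cluster count $k$ strongly affects the high-order network; the nested CV
  treats it as a hyper-parameter, but cluster *composition* can differ
  between folds, so selection frequencies for high-order features are
  tracked per $k$ and reported for the modally chosen $k$ only.
* The region annotation covers the five coarse scalp regions of the
  128-channel geodesic montage; the finer left/right sub-division described
  in the literature has no published channel-level assignment and is not
  emulated.
* Recorded-EEG preprocessing (re-referencing, artifact subspace
  reconstruction, notch filtering) is out of scope; inputs are assumed
  clean.
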