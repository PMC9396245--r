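#' Synthetic study configuration
#'
#' Defaults define the synthetic validation study: two groups of 10
#' subjects, 12 channels in G = 3 equal modules, 250 Hz, 10-minute
#' recordings (150000 samples, giving H = 141 windows under the windowing
#' defaults W = 10000, s = 1000 — enough windows for stable
#' correlation-of-correlation estimates), coupling state piecewise-constant
#' over 250-sample (1 s) segments following smooth stationary latent
#' courses, additive noise at 10% of the unit oscillation amplitude, and a
#' high-order group effect of delta = 2 (expected between-module course
#' correlation delta/sqrt(1+delta^2) ~= 0.89 in the MDD-like group versus 0
#' in controls).
#'
#' @param RPerGroup subjects per group.
#' @param E channels.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param G module count.
#' @param segLen coupling-segment length (samples).
#' @param noiseSd relative noise SD.
#' @param delta high-order effect size (mixing coefficient).
#' @param seed RNG seed.
#' @return a \code{SynthConfig}.
#' @export
synthConfig <- function(RPerGroup = 10, E = 12, fs = 250, duration = 600,
                        G = 3, segLen = 250, noiseSd = 0.1, delta = 2,
                        seed = 1) {
  new("SynthConfig", RPerGroup = as.integer(RPerGroup), E = as.integer(E),
      fs = as.numeric(fs), duration = as.numeric(duration),
      G = as.integer(G), segLen = as.integer(segLen),
      noiseSd = as.numeric(noiseSd), delta = as.numeric(delta),
      seed = as.integer(seed))
}

# Standardized stationary AR(1) course (phi = 0.8): smooth, slowly drifting
# but mean-reverting, so between-module correlations have a well-behaved
# null (a nonstationary walk would generate spurious correlations).
.latentCourse <- function(n, phi = 0.8) {
  e <- stats::rnorm(n + 50L)
  z <- stats::filter(e, phi, method = "recursive")[-(1:50)]
  z <- as.numeric(z)
  if (stats::sd(z) == 0) return(rep(0, n))
  (z - mean(z)) / stats::sd(z)
}

# Mix module 2's course toward module 1's: corr -> delta/sqrt(1+delta^2).
.mixCourses <- function(Z, delta) {
  if (nrow(Z) >= 2L && delta > 0) {
    m <- Z[2L, ] + delta * Z[1L, ]
    Z[2L, ] <- (m - mean(m)) / stats::sd(m)
  }
  Z
}

.synthSubjectIds <- function(cfg) {
  c(sprintf("mdd%02d", seq_len(cfg@RPerGroup)),
    sprintf("nc%02d", seq_len(cfg@RPerGroup)))
}

#' Generate synthetic connectivity time series
#'
#' Directly emulates the statistical structure that the high-order stage
#' consumes: each pair's connectivity time series is its module's smooth
#' latent course (standardized stationary AR(1) over the H windows) plus Gaussian
#' noise; in the MDD-like group the courses of modules 1 and 2 are mixed by
#' \code{delta}, shifting their correlation. Pairs are assigned to modules
#' in contiguous blocks.
#'
#' @param cfg a \code{SynthConfig} (RPerGroup, G, noiseSd, delta, seed are
#'   used).
#' @param H number of windows per subject.
#' @param P number of pair series per subject; defaults to
#'   \code{choose(E, 2)}.
#' @return list with \code{series} (list of \code{FCSeriesMatrix}),
#'   \code{y} (labels, MDD = -1), \code{subjects} and \code{truth}
#'   (\code{modules}: planted pair-to-module assignment; \code{mixed}: the
#'   affected module pair; \code{courses}: per-subject latent courses).
#' @export
genFCSeries <- function(cfg, H, P = choose(cfg@E, 2)) {
  stopifnot(is(cfg, "SynthConfig"), H >= 3, P >= cfg@G)
  set.seed(cfg@seed)
  moduleOf <- sort(rep_len(seq_len(cfg@G), P))
  subjects <- .synthSubjectIds(cfg)
  y <- c(rep(-1, cfg@RPerGroup), rep(1, cfg@RPerGroup))
  courses <- list()
  series <- vector("list", length(subjects))
  for (l in seq_along(subjects)) {
    Z <- t(vapply(seq_len(cfg@G), function(g) .latentCourse(H), numeric(H)))
    if (y[l] == -1) Z <- .mixCourses(Z, cfg@delta)
    S <- Z[moduleOf, , drop = FALSE] +
      cfg@noiseSd * matrix(stats::rnorm(P * H), P, H)
    courses[[subjects[l]]] <- Z
    series[[l]] <- new("FCSeriesMatrix", subjectId = subjects[l],
                       series = S, band = "synthetic", method = "pli")
  }
  list(series = series, y = y, subjects = subjects,
       truth = list(modules = moduleOf, mixed = c(1L, 2L),
                    courses = courses))
}

# Generate one subject's EEG given module on/off states (G x nSeg). While a
# module is on, its channels share the module oscillation (carrier plus a
# common random phase offset redrawn every segment) shifted by their fixed
# lags, so within-module pairs are phase-locked. While off, a channel's
# phase is independent uniform noise per sample. Every uncoupled channel
# relation (off-off, on-off, and on-on across modules, whose carriers also
# decohere through the per-segment offsets) therefore reduces to
# statistically identical independent phases, so no pair's low-order
# connectivity carries a signature of the joint on/off dynamics: the planted
# group effect lives only in the correlation BETWEEN module courses.
.genSubjectEEG <- function(cfg, states, carriers, moduleOf, lags, id) {
  nSeg <- ncol(states)
  M <- nSeg * cfg@segLen
  tIdx <- (seq_len(M) - 1) / cfg@fs
  offs <- matrix(stats::runif(cfg@G * nSeg, -pi, pi), cfg@G, nSeg)
  data <- matrix(0, cfg@E, M)
  for (ch in seq_len(cfg@E)) {
    g <- moduleOf[ch]
    phase <- 2 * pi * carriers[g] * tIdx + lags[ch] +
      rep(offs[g, ], each = cfg@segLen)
    off <- !states[g, rep(seq_len(nSeg), each = cfg@segLen)]
    nOff <- sum(off)
    if (nOff > 0L)
      phase[off] <- stats::runif(nOff, -pi, pi)
    data[ch, ] <- cos(phase)
  }
  if (cfg@noiseSd > 0)
    data <- data + cfg@noiseSd * matrix(stats::rnorm(cfg@E * M), cfg@E, M)
  new("EEGRecording", subjectId = id, data = data, fs = cfg@fs,
      channelLabels = paste0("ch", seq_len(cfg@E)), band = "time")
}

#' Generate synthetic band-limited EEG with planted phase coupling
#'
#' Each module has a carrier frequency in the alpha band and a smooth latent
#' course over coupling segments; while a module is "on" (course above its
#' median sign threshold) its channels hold fixed phase lags (spread over
#' (0, pi/2], so every within-module pair has a nonzero lag), giving
#' phase-lag-index values near 1; while "off", channels drift at privately
#' jittered frequencies, giving values near 0. In the MDD-like group the
#' latent courses of modules 1 and 2 are mixed by \code{delta} before
#' thresholding, correlating their on/off dynamics: a purely high-order
#' group difference, since each module's marginal on-fraction is unchanged.
#'
#' @param cfg a \code{SynthConfig}.
#' @return list with \code{recordings} (list of \code{EEGRecording}),
#'   \code{y}, \code{subjects} and \code{truth} (\code{moduleOf} per
#'   channel, \code{lags}, \code{carriers}, and per-subject on/off
#'   \code{states} G x nSeg).
#' @export
genEEG <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  M <- floor(cfg@fs * cfg@duration)
  nSeg <- M %/% cfg@segLen
  stopifnot(nSeg >= 2L)
  set.seed(cfg@seed)
  moduleOf <- sort(rep_len(seq_len(cfg@G), cfg@E))
  # per-channel lags spread over (0, pi/2] within each module
  lags <- numeric(cfg@E)
  for (g in seq_len(cfg@G)) {
    mem <- which(moduleOf == g)
    lags[mem] <- (seq_along(mem) - 1) * pi / (2 * length(mem))
  }
  carriers <- 9 + (seq_len(cfg@G) - 1) * 1.2
  subjects <- .synthSubjectIds(cfg)
  y <- c(rep(-1, cfg@RPerGroup), rep(1, cfg@RPerGroup))
  recs <- vector("list", length(subjects))
  states <- list()
  for (l in seq_along(subjects)) {
    Z <- t(vapply(seq_len(cfg@G), function(g) .latentCourse(nSeg),
                  numeric(nSeg)))
    if (y[l] == -1) Z <- .mixCourses(Z, cfg@delta)
    st <- Z > 0
    states[[subjects[l]]] <- st
    recs[[l]] <- .genSubjectEEG(cfg, st, carriers, moduleOf, lags,
                                subjects[l])
  }
  list(recordings = recs, y = y, subjects = subjects,
       truth = list(moduleOf = moduleOf, lags = lags, carriers = carriers,
                    states = states, mixed = c(1L, 2L)))
}

#' Planted coupling course at window resolution
#'
#' Converts a subject's segment-level on/off states into the expected
#' windowed coupling course for each module under a window plan: the
#' fraction of "on" samples in each window.
#'
#' @param states logical G x nSeg matrix from \code{genEEG}'s truth.
#' @param segLen segment length in samples.
#' @param plan a \code{WindowPlan}.
#' @return numeric G x H matrix.
#' @export
plantedCouplingSeries <- function(states, segLen, plan) {
  perSample <- states[, rep(seq_len(ncol(states)), each = segLen),
                      drop = FALSE]
  out <- vapply(seq_len(plan@H), function(h) {
    idx <- (plan@starts[h] + 1L):(plan@starts[h] + plan@W)
    rowMeans(perSample[, idx, drop = FALSE])
  }, numeric(nrow(states)))
  matrix(out, nrow = nrow(states))
}

#' Generate a full pipeline-ready synthetic dataset
#'
#' \code{genEEG} plus a manifest; when \code{dir} is given, each recording
#' is written in the delimited matrix format with its JSON sidecar together
#' with \code{manifest.csv}, byte-identically reproducible from the seed.
#'
#' @param cfg a \code{SynthConfig}.
#' @param dir optional output directory.
#' @return as \code{genEEG}, plus \code{manifest} (data.frame) and, when
#'   written, \code{dir}.
#' @export
genDataset <- function(cfg, dir = NULL) {
  out <- genEEG(cfg)
  out$manifest <- data.frame(
    subject_id = out$subjects,
    path = paste0(out$subjects, ".csv"),
    label = ifelse(out$y == -1, "MDD", "NC"),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (rec in out$recordings)
      writeRecording(rec, file.path(dir, paste0(rec@subjectId, ".csv")))
    utils::write.csv(out$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    out$dir <- dir
  }
  out
}
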