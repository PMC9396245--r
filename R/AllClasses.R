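#' @import methods
NULL

.checkNumericMatrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    return(sprintf("%s must be a numeric matrix", what))
  if (any(!is.finite(x)))
    return(sprintf("%s contains missing or non-finite values", what))
  NULL
}

#' EEGRecording: a multichannel EEG recording
#'
#' Container for one subject's multichannel EEG. Channels are rows, samples
#' are columns; the optional \code{band} tag records which frequency band the
#' signal has been restricted to (\code{"time"} means broadband/unfiltered).
#'
#' @slot subjectId single subject identifier.
#' @slot data numeric matrix, E channels x M samples (microvolts or
#'   arbitrary units).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of E unique channel names.
#' @slot band band tag, e.g. \code{"time"}, \code{"theta"}, \code{"alpha"},
#'   \code{"beta"}.
#' @exportClass EEGRecording
setClass("EEGRecording",
  slots = c(subjectId = "character", data = "matrix", fs = "numeric",
            channelLabels = "character", band = "character"),
  prototype = prototype(band = "time"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@data, "data")
    if (!is.null(msg)) return(msg)
    if (nrow(object@data) < 2L) return("need at least 2 channels")
    if (ncol(object@data) < 2L) return("need at least 2 samples")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      return("fs must be a single positive number")
    if (length(object@channelLabels) != nrow(object@data))
      return("channelLabels must have one entry per channel")
    if (anyDuplicated(object@channelLabels))
      return("channelLabels must be unique")
    if (length(object@subjectId) != 1L) return("subjectId must be length 1")
    if (length(object@band) != 1L) return("band must be length 1")
    TRUE
  })

#' BandSpec: a frequency band
#'
#' @slot name band name.
#' @slot low lower edge in Hz (exclusive of 0).
#' @slot high upper edge in Hz; must stay below the Nyquist frequency of any
#'   recording it is applied to.
#' @exportClass BandSpec
setClass("BandSpec",
  slots = c(name = "character", low = "numeric", high = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be length 1")
    if (length(object@low) != 1L || length(object@high) != 1L)
      return("low and high must be single numbers")
    if (!(object@low > 0 && object@high > object@low))
      return("need 0 < low < high")
    TRUE
  })

#' PhaseSeries: instantaneous phase per channel
#'
#' Phases of the analytic signal, wrapped to (-pi, pi].
#'
#' @slot data numeric matrix E x M of phases in radians.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels channel names.
#' @slot subjectId subject identifier.
#' @slot band band tag inherited from the filtered recording.
#' @exportClass PhaseSeries
setClass("PhaseSeries",
  slots = c(subjectId = "character", data = "matrix", fs = "numeric",
            channelLabels = "character", band = "character"),
  prototype = prototype(band = "time"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@data, "data")
    if (!is.null(msg)) return(msg)
    eps <- 1e-9
    if (any(object@data > pi + eps) || any(object@data <= -pi - eps))
      return("phases must lie in (-pi, pi]")
    if (length(object@channelLabels) != nrow(object@data))
      return("channelLabels must have one entry per channel")
    TRUE
  })

#' WindowPlan: sliding-window layout
#'
#' Overlapping windows of width \code{W} advanced by step \code{s} over a
#' recording of \code{M} samples; the window count is
#' H = floor((M - W)/s) + 1. Starts are 0-based and windows are half-open
#' [start, start + W), so tests against explicit indices are exact.
#'
#' @slot M total samples.
#' @slot W window width in samples.
#' @slot s step in samples.
#' @slot H number of windows.
#' @slot starts integer vector of H 0-based start indices.
#' @exportClass WindowPlan
setClass("WindowPlan",
  slots = c(M = "integer", W = "integer", s = "integer", H = "integer",
            starts = "integer"),
  validity = function(object) {
    with_slots <- c(object@M, object@W, object@s, object@H)
    if (any(is.na(with_slots))) return("plan fields must be non-missing")
    if (object@H != length(object@starts)) return("H must match starts")
    if (object@H < 1L) return("need at least one window")
    if (object@starts[1L] != 0L) return("first window must start at 0")
    if (object@starts[object@H] + object@W > object@M)
      return("last window exceeds the recording")
    TRUE
  })

#' DynamicFC: windowed low-order connectivity tensor
#'
#' One subject's low-order brain functional network: an H x E x E stack of
#' per-window connectivity matrices (phase lag index or Pearson correlation).
#'
#' @slot subjectId subject identifier.
#' @slot method \code{"pli"} or \code{"pcc"}.
#' @slot band band tag inherited from the input recording.
#' @slot tensor numeric array H x E x E.
#' @slot channelLabels channel names (length E).
#' @exportClass DynamicFC
setClass("DynamicFC",
  slots = c(subjectId = "character", method = "character", band = "character",
            tensor = "array", channelLabels = "character"),
  validity = function(object) {
    if (!object@method %in% c("pli", "pcc"))
      return("method must be 'pli' or 'pcc'")
    d <- dim(object@tensor)
    if (length(d) != 3L || d[2L] != d[3L])
      return("tensor must be H x E x E")
    if (length(object@channelLabels) != d[2L])
      return("channelLabels must have length E")
    if (any(!is.finite(object@tensor))) return("tensor has non-finite values")
    tol <- 1e-8
    for (h in seq_len(d[1L])) {
      S <- object@tensor[h, , ]
      if (max(abs(S - t(S))) > tol) return("window matrices must be symmetric")
      if (object@method == "pli") {
        if (any(S < -tol) || any(S > 1 + tol)) return("PLI entries must be in [0,1]")
        if (max(abs(diag(S))) > tol) return("PLI diagonal must be 0")
      } else {
        if (any(S < -1 - tol) || any(S > 1 + tol))
          return("PCC entries must be in [-1,1]")
        if (max(abs(diag(S) - 1)) > tol) return("PCC diagonal must be 1")
      }
    }
    TRUE
  })

#' FCSeriesMatrix: per-pair connectivity time series
#'
#' P x H matrix whose row r is the connectivity time series of channel pair r
#' across the H windows, in canonical pair order (i < j, lexicographic).
#' Synthetic series generated directly at the pair level may omit channel
#' metadata (\code{pairs} with zero rows).
#'
#' @slot subjectId subject identifier.
#' @slot series numeric matrix P x H.
#' @slot pairs integer matrix P x 2 of (i, j) channel indices, or 0-row.
#' @slot channelLabels channel names, or empty.
#' @slot band band tag.
#' @slot method connectivity method tag.
#' @exportClass FCSeriesMatrix
setClass("FCSeriesMatrix",
  slots = c(subjectId = "character", series = "matrix", pairs = "matrix",
            channelLabels = "character", band = "character",
            method = "character"),
  prototype = prototype(pairs = matrix(integer(), 0L, 2L),
                        channelLabels = character(), band = "time",
                        method = "pli"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@series, "series")
    if (!is.null(msg)) return(msg)
    if (nrow(object@pairs) > 0L) {
      if (ncol(object@pairs) != 2L) return("pairs must have two columns")
      if (nrow(object@pairs) != nrow(object@series))
        return("pairs must have one row per series row")
      if (any(object@pairs[, 1L] >= object@pairs[, 2L]))
        return("pairs must satisfy i < j")
    }
    TRUE
  })

#' GroupSeriesStack: cross-subject long vectors
#'
#' Row r is the concatenation of pair r's connectivity time series over all
#' subjects in ascending subject order, the "long vector" clustered to define
#' consistent pair clusters across subjects.
#'
#' @slot series numeric matrix P x (R*H).
#' @slot subjectIds subjects in concatenation order.
#' @slot H per-subject window count.
#' @slot pairs pair index (possibly 0-row).
#' @exportClass GroupSeriesStack
setClass("GroupSeriesStack",
  slots = c(series = "matrix", subjectIds = "character", H = "integer",
            pairs = "matrix"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@series, "series")
    if (!is.null(msg)) return(msg)
    if (ncol(object@series) != length(object@subjectIds) * object@H)
      return("series width must equal R * H")
    TRUE
  })

#' ClusterAssignment: pair-to-cluster map
#'
#' @slot labels integer vector of cluster ids in 1..k, one per pair.
#' @slot k number of clusters.
#' @slot linkage linkage description (e.g. "ward.D2/euclidean").
#' @slot fittedOn subject ids whose long vectors the tree was fitted on.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  slots = c(labels = "integer", k = "integer", linkage = "character",
            fittedOn = "character"),
  validity = function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (any(object@labels < 1L | object@labels > object@k))
      return("labels must lie in 1..k")
    if (!all(seq_len(object@k) %in% object@labels))
      return("every cluster id in 1..k must occur")
    TRUE
  })

#' ClusterMeanSeries: per-cluster mean connectivity series
#'
#' Row g is the arithmetic mean of the subject's pair series assigned to
#' cluster g.
#'
#' @slot subjectId subject identifier.
#' @slot series numeric matrix k x H.
#' @exportClass ClusterMeanSeries
setClass("ClusterMeanSeries",
  slots = c(subjectId = "character", series = "matrix"),
  validity = function(object) .checkNumericMatrix(object@series, "series") %||% TRUE)

#' HOBFNMatrix: clustered high-order network
#'
#' k x k matrix of Pearson correlations between cluster-mean connectivity
#' series ("correlation's correlation"); symmetric with unit diagonal.
#'
#' @slot subjectId subject identifier.
#' @slot mat numeric k x k matrix.
#' @exportClass HOBFNMatrix
setClass("HOBFNMatrix",
  slots = c(subjectId = "character", mat = "matrix"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@mat, "mat")
    if (!is.null(msg)) return(msg)
    tol <- 1e-8
    if (nrow(object@mat) != ncol(object@mat)) return("mat must be square")
    if (max(abs(object@mat - t(object@mat))) > tol)
      return("mat must be symmetric")
    if (max(abs(diag(object@mat) - 1)) > tol)
      return("mat must have unit diagonal")
    if (any(object@mat < -1 - tol) || any(object@mat > 1 + tol))
      return("entries must be in [-1,1]")
    TRUE
  })

#' FeatureSet: subjects-by-features design matrix
#'
#' @slot subjectIds subject identifiers (rows of X).
#' @slot X numeric matrix R x d.
#' @slot kind \code{"low"} (d = P averaged pair connectivities) or
#'   \code{"high"} (d = k(k-1)/2 vectorized high-order edges).
#' @slot provenance free-form list (band, method, k, ...).
#' @exportClass FeatureSet
setClass("FeatureSet",
  slots = c(subjectIds = "character", X = "matrix", kind = "character",
            provenance = "list"),
  validity = function(object) {
    msg <- .checkNumericMatrix(object@X, "X")
    if (!is.null(msg)) return(msg)
    if (!object@kind %in% c("low", "high"))
      return("kind must be 'low' or 'high'")
    if (nrow(object@X) != length(object@subjectIds))
      return("X must have one row per subject")
    TRUE
  })

#' SelectionMask: a feature-selection stage
#'
#' Records which feature indices a screening/selection stage kept and which
#' subjects it was fitted on (the leakage audit field).
#'
#' @slot stage \code{"ttest"} or \code{"lasso"}.
#' @slot kept strictly increasing indices into the parent feature space.
#' @slot fittedOn subject ids the stage was fitted on.
#' @slot detail stage-specific extras (p-values, LASSO weights).
#' @exportClass SelectionMask
setClass("SelectionMask",
  slots = c(stage = "character", kept = "integer", fittedOn = "character",
            detail = "list"),
  validity = function(object) {
    if (!object@stage %in% c("ttest", "lasso"))
      return("stage must be 'ttest' or 'lasso'")
    if (length(object@kept) > 1L && any(diff(object@kept) <= 0L))
      return("kept indices must be strictly increasing")
    TRUE
  })

#' LinearSVMModel: a trained linear soft-margin SVM
#'
#' Decision score d(x) = <w, x> + b; positive scores predict the +1 class.
#'
#' @slot w weight vector.
#' @slot b bias.
#' @slot cost soft-margin cost parameter.
#' @exportClass LinearSVMModel
setClass("LinearSVMModel",
  slots = c(w = "numeric", b = "numeric", cost = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@w)) || !is.finite(object@b))
      return("w and b must be finite")
    if (object@cost <= 0) return("cost must be positive")
    TRUE
  })

#' EvalMetrics: binary classification metrics
#'
#' Six metrics as percentages with the depressed (MDD, label -1) group as the
#' positive class, plus the confusion counts they derive from. Ratios with a
#' zero denominator are NaN.
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot acc,tpr,tnr,ppv,npv,f1 metrics in percent.
#' @exportClass EvalMetrics
setClass("EvalMetrics",
  slots = c(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
            acc = "numeric", tpr = "numeric", tnr = "numeric",
            ppv = "numeric", npv = "numeric", f1 = "numeric"))

#' CVConfig: nested cross-validation configuration
#'
#' Hyper-parameter grids and fold structure for the nested repeated
#' stratified cross-validation. The default grids follow the full study
#' protocol (k in 100..800, p in 0.01..0.05, lambda in 0.1..0.9, c in
#' 2^-4..2^4, ten outer and inner folds, ten repeats); \code{synthCVConfig}
#' provides the reduced grids used for the synthetic validation study.
#'
#' @slot outerFolds,innerFolds,repeats fold structure.
#' @slot seed integer RNG seed controlling all partitions.
#' @slot kGrid cluster-count grid (clipped to the number of pairs at fit time).
#' @slot pGrid t-test significance-level grid.
#' @slot lambdaGrid LASSO regularization grid.
#' @slot cGrid SVM cost grid.
#' @slot paperFaithful if TRUE, pair clustering is fitted on the long vectors
#'   of all subjects (the original all-subject protocol); if FALSE (default),
#'   on training subjects only, the assignment transferring verbatim to test
#'   subjects because pairs are shared.
#' @exportClass CVConfig
setClass("CVConfig",
  slots = c(outerFolds = "integer", innerFolds = "integer",
            repeats = "integer", seed = "integer", kGrid = "numeric",
            pGrid = "numeric", lambdaGrid = "numeric", cGrid = "numeric",
            paperFaithful = "logical"),
  validity = function(object) {
    if (object@outerFolds < 2L || object@innerFolds < 2L)
      return("need at least 2 folds")
    if (object@repeats < 1L) return("repeats must be >= 1")
    if (any(object@kGrid < 1)) return("kGrid must be >= 1")
    if (any(object@pGrid <= 0 | object@pGrid > 1))
      return("pGrid must be in (0, 1]")
    if (any(object@lambdaGrid < 0)) return("lambdaGrid must be >= 0")
    if (any(object@cGrid <= 0)) return("cGrid must be > 0")
    TRUE
  })

#' SynthConfig: synthetic-data generator configuration
#'
#' Defines the synthetic study conditions: band-limited oscillatory EEG with
#' G channel modules whose within-module phase coupling switches on and off
#' over coupling segments following smooth latent courses; in the MDD-like
#' group the courses of two chosen modules are mixed so their correlation is
#' shifted (a high-order group effect that leaves window-averaged low-order
#' connectivity unchanged in expectation).
#'
#' @slot RPerGroup subjects per group.
#' @slot E channels.
#' @slot fs sampling rate (Hz).
#' @slot duration recording length (s).
#' @slot G planted module count.
#' @slot segLen coupling-segment length in samples (coupling state is
#'   constant within a segment).
#' @slot noiseSd additive noise SD relative to unit signal amplitude.
#' @slot delta effect size: the affected module course becomes
#'   standardize(z2 + delta * z1), giving expected course correlation
#'   delta/sqrt(1 + delta^2).
#' @slot seed integer RNG seed.
#' @exportClass SynthConfig
setClass("SynthConfig",
  slots = c(RPerGroup = "integer", E = "integer", fs = "numeric",
            duration = "numeric", G = "integer", segLen = "integer",
            noiseSd = "numeric", delta = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@RPerGroup < 1L) return("RPerGroup must be >= 1")
    if (object@E < 2L) return("need at least 2 channels")
    if (object@fs <= 0 || object@duration <= 0)
      return("fs and duration must be positive")
    if (object@G < 1L || object@G > object@E)
      return("G must be in 1..E")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@delta < 0) return("delta must be >= 0")
    TRUE
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
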