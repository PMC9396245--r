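#' Plan sliding windows
#'
#' Divides M samples into H = floor((M - W)/s) + 1 overlapping windows of
#' width W advanced by step s. Windows are 0-based and half-open,
#' [start, start + W), so the last window always fits inside the recording.
#'
#' @param M total number of samples.
#' @param W window width in samples (1 <= W <= M).
#' @param s step in samples (>= 1).
#' @return a \code{WindowPlan}.
#' @examples
#' planWindows(75000, 10000, 1000)  # H = 66
#' @export
planWindows <- function(M, W, s) {
  M <- as.integer(M); W <- as.integer(W); s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("step s must be >= 1")
  if (is.na(W) || W < 1L) stop("window width W must be >= 1")
  if (W > M) stop("window width W (", W, ") exceeds the recording length M (",
                  M, ")")
  H <- (M - W) %/% s + 1L
  new("WindowPlan", M = M, W = W, s = s, H = H,
      starts = as.integer(seq(0L, by = s, length.out = H)))
}

#' Phase lag index matrix for one window
#'
#' PLI(i, j) = |(1/N) sum_n sign(wrap(phi_i(t_n) - phi_j(t_n)))| with the
#' phase difference wrapped via sign(sin(.)), the standard PLI definition:
#' the asymmetry of the phase-difference distribution around zero. Values lie
#' in [0, 1]; the diagonal is 0; zero-lag (volume-conduction) coupling gives
#' 0.
#'
#' @param phases numeric matrix E x N of phases (radians), e.g. a window
#'   slice of a \code{PhaseSeries}.
#' @return symmetric E x E matrix.
#' @export
pliMatrix <- function(phases) {
  if (is(phases, "PhaseSeries")) phases <- phases@data
  stopifnot(is.matrix(phases), nrow(phases) >= 2L, ncol(phases) >= 1L)
  E <- nrow(phases)
  N <- ncol(phases)
  P <- matrix(0, E, E)
  for (i in seq_len(E - 1L)) {
    for (j in (i + 1L):E) {
      v <- abs(sum(sign(sin(phases[i, ] - phases[j, ]))) / N)
      P[i, j] <- v
      P[j, i] <- v
    }
  }
  P
}

#' Pearson correlation matrix for one window
#'
#' Entry (i, j) is the Pearson correlation of channels i and j over the
#' window; symmetric with unit diagonal. A channel that is constant within
#' the window has no defined correlation; its entries are set to 0 with a
#' warning so pipelines stay total.
#'
#' @param window numeric matrix E x W of signal samples.
#' @return symmetric E x E matrix.
#' @export
pccMatrix <- function(window) {
  if (is(window, "EEGRecording")) window <- window@data
  stopifnot(is.matrix(window), nrow(window) >= 2L, ncol(window) >= 2L)
  .safeCorRows(window)
}

#' Build the windowed low-order network
#'
#' Stacks the per-window connectivity matrices defined by \code{plan} into a
#' \code{DynamicFC}. \code{method = "pli"} consumes a \code{PhaseSeries} (the
#' phase is computed once on the full recording; windows slice it),
#' \code{method = "pcc"} consumes an \code{EEGRecording}.
#'
#' @param x a \code{PhaseSeries} (pli) or \code{EEGRecording} (pcc).
#' @param plan a \code{WindowPlan} for the same number of samples.
#' @param method \code{"pli"} or \code{"pcc"}.
#' @return a \code{DynamicFC} with tensor H x E x E.
#' @export
buildDynamicFC <- function(x, plan, method = c("pli", "pcc")) {
  method <- match.arg(method)
  stopifnot(is(plan, "WindowPlan"))
  if (method == "pli" && !is(x, "PhaseSeries"))
    stop("method 'pli' needs a PhaseSeries")
  if (method == "pcc" && !is(x, "EEGRecording"))
    stop("method 'pcc' needs an EEGRecording")
  dat <- x@data
  if (ncol(dat) != plan@M)
    stop("window plan was made for M=", plan@M, " but the input has ",
         ncol(dat), " samples")
  E <- nrow(dat)
  H <- plan@H
  W <- plan@W
  tensor <- array(0, c(H, E, E))
  if (method == "pli") {
    # sign(sin(dphi)) over the full series once per pair; windowed means via
    # cumulative sums (exact: summands are -1/0/1).
    pr <- pairIndex(E)
    a <- plan@starts + 1L
    b <- plan@starts + W
    for (r in seq_len(nrow(pr))) {
      i <- pr[r, 1L]; j <- pr[r, 2L]
      cs <- c(0, cumsum(sign(sin(dat[i, ] - dat[j, ]))))
      v <- abs((cs[b + 1L] - cs[a]) / W)
      tensor[, i, j] <- v
      tensor[, j, i] <- v
    }
  } else {
    for (h in seq_len(H)) {
      sl <- dat[, (plan@starts[h] + 1L):(plan@starts[h] + W), drop = FALSE]
      tensor[h, , ] <- pccMatrix(sl)
    }
  }
  new("DynamicFC", subjectId = x@subjectId, method = method,
      band = x@band, tensor = tensor, channelLabels = x@channelLabels)
}

#' Vectorize a dynamic network into per-pair time series
#'
#' Returns the P x H matrix whose row r is the connectivity time series of
#' canonical pair r: the low-order connectivity time series that high-order
#' network construction operates on.
#'
#' @param fc a \code{DynamicFC}.
#' @return an \code{FCSeriesMatrix}.
#' @export
toSeries <- function(fc) {
  stopifnot(is(fc, "DynamicFC"))
  d <- dim(fc@tensor)
  pr <- pairIndex(d[2L])
  series <- vapply(seq_len(d[1L]),
                   function(h) fc@tensor[h, , ][pr],
                   numeric(nrow(pr)))
  if (is.null(dim(series))) series <- matrix(series, nrow = nrow(pr))
  new("FCSeriesMatrix", subjectId = fc@subjectId, series = series,
      pairs = pr, channelLabels = fc@channelLabels, band = fc@band,
      method = fc@method)
}
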