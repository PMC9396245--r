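#' Frequency band specifications
#'
#' \code{bandSpec} builds a band; \code{standardBands} returns the three
#' rhythms used throughout the package: theta (4-8 Hz), alpha (8-13 Hz) and
#' beta (13-40 Hz).
#'
#' @param name band name.
#' @param low,high band edges in Hz.
#' @return a \code{BandSpec}, or for \code{standardBands} a named list of
#'   them.
#' @examples
#' standardBands()$alpha
#' @export
bandSpec <- function(name, low, high) {
  new("BandSpec", name = as.character(name), low = as.numeric(low),
      high = as.numeric(high))
}

#' @rdname bandSpec
#' @export
standardBands <- function() {
  list(theta = bandSpec("theta", 4, 8),
       alpha = bandSpec("alpha", 8, 13),
       beta  = bandSpec("beta", 13, 40))
}

#' Band-limit a recording with a hard DFT mask
#'
#' Per channel: forward DFT, zero every bin whose frequency magnitude falls
#' outside [low, high], inverse DFT. The mask is an ideal (brick-wall)
#' filter, so the operation is an orthogonal projection: it is idempotent and
#' the passband and stopband energies sum to the input energy. Signal length
#' is unchanged; components that are not exact DFT bins leak slightly across
#' the band edges, which matters only near the edges of short recordings.
#'
#' @param rec an \code{EEGRecording}.
#' @param band a \code{BandSpec}; must satisfy high < fs/2.
#' @return an \code{EEGRecording} tagged with the band's name.
#' @export
bandpass <- function(rec, band) {
  stopifnot(is(rec, "EEGRecording"), is(band, "BandSpec"))
  fs <- rec@fs
  if (band@high >= fs / 2)
    stop("band '", band@name, "' exceeds the Nyquist frequency ", fs / 2,
         " Hz")
  M <- ncol(rec@data)
  f <- (seq_len(M) - 1L) * fs / M
  f <- ifelse(f > fs / 2, f - fs, f)
  keep <- abs(f) >= band@low & abs(f) <= band@high
  filt <- t(apply(rec@data, 1L, function(x) {
    X <- stats::fft(x)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / M
  }))
  dimnames(filt) <- NULL
  new("EEGRecording", subjectId = rec@subjectId, data = filt, fs = fs,
      channelLabels = rec@channelLabels, band = band@name)
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert analytic signal of each channel over the full
#' recording (phase is extracted before windowing so per-window edge
#' artifacts are avoided; windows later slice this phase series) and returns
#' its argument wrapped to (-pi, pi].
#'
#' @param rec an \code{EEGRecording}; every channel must have nonzero
#'   variance.
#' @return a \code{PhaseSeries}.
#' @export
instantaneousPhase <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  M <- ncol(rec@data)
  vars <- apply(rec@data, 1L, stats::var)
  if (any(vars == 0))
    stop("constant channel(s): ",
         paste(rec@channelLabels[vars == 0], collapse = ", "),
         " (analytic phase undefined)")
  h <- numeric(M)
  if (M %% 2L == 0L) {
    h[1L] <- 1
    h[2:(M / 2)] <- 2
    h[M / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((M + 1L) / 2)] <- 2
  }
  ph <- t(apply(rec@data, 1L, function(x) {
    z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / M
    Arg(z)
  }))
  dimnames(ph) <- NULL
  new("PhaseSeries", subjectId = rec@subjectId, data = ph, fs = rec@fs,
      channelLabels = rec@channelLabels, band = rec@band)
}
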