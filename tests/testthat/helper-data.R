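# Small builders shared across test files.

makeRecording <- function(data, fs = 250, id = "s1", band = "time") {
  new("EEGRecording", subjectId = id, data = data, fs = fs,
      channelLabels = paste0("ch", seq_len(nrow(data))), band = band)
}

sineRecording <- function(freqs, fs = 250, M = 500, phases = NULL, id = "s1") {
  t <- (seq_len(M) - 1) / fs
  if (is.null(phases)) phases <- rep(0, length(freqs))
  makeRecording(t(mapply(function(f, p) cos(2 * pi * f * t + p), freqs,
                         phases)), fs = fs, id = id)
}

makeSeries <- function(mat, id = "s1") {
  new("FCSeriesMatrix", subjectId = id, series = mat, band = "synthetic",
      method = "pli")
}

makeAssignment <- function(labels, k = max(labels), fittedOn = "s1") {
  new("ClusterAssignment", labels = as.integer(labels), k = as.integer(k),
      linkage = "ward.D2/euclidean", fittedOn = fittedOn)
}

signalEnergy <- function(x) sum(x^2)

# Minimal EDF writer (independent of the package reader): 16-bit continuous
# EDF with one data record per second.
writeTestEDF <- function(path, data, fs, physMin = -200, physMax = 200,
                         sprOverride = NULL) {
  ns <- nrow(data)
  recDur <- 1
  spr <- rep(as.integer(fs * recDur), ns)
  if (!is.null(sprOverride)) spr <- sprOverride
  nRec <- ncol(data) %/% max(spr)
  pad <- function(x, w) {
    s <- substr(format(x, width = w), 1, w)
    sprintf(paste0("%-", w, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test rec", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 + 256 * ns, 8), pad("", 44), pad(nRec, 8),
                pad(recDur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(sapply(vals, pad, w),
                                            collapse = ""), con, eos = NULL)
  fld(paste0("sig", seq_len(ns)), 16)   # labels
  fld(rep("", ns), 80)                  # transducer
  fld(rep("uV", ns), 8)                 # physical dimension
  fld(rep(physMin, ns), 8)
  fld(rep(physMax, ns), 8)
  fld(rep(-32768, ns), 8)
  fld(rep(32767, ns), 8)
  fld(rep("", ns), 80)                  # prefiltering
  fld(spr, 8)
  fld(rep("", ns), 32)                  # reserved
  dig <- round((data - physMin) / (physMax - physMin) * 65535 - 32768)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      idx <- idx[idx <= ncol(data)]
      seg <- dig[i, idx]
      writeBin(as.integer(c(seg, rep(0, spr[i] - length(seg)))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}
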