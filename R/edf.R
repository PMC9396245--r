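# Minimal EDF (European Data Format) reader: 256-byte fixed-width ASCII
# header, 256 bytes of signal header fields per signal, then data records of
# 16-bit little-endian two's-complement samples scaled linearly from digital
# to physical range. Continuous EDF only; annotation channels and EDF+
# discontinuous files are not supported.

.edfField <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1L):(off + len)]))
}

.readEDF <- function(path, subjectId) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("unreadable EDF: truncated header in ", path)
  nHeaderBytes <- suppressWarnings(as.integer(.edfField(hdr, 184L, 8L)))
  nRecords <- suppressWarnings(as.integer(.edfField(hdr, 236L, 8L)))
  recDur <- suppressWarnings(as.numeric(.edfField(hdr, 244L, 8L)))
  ns <- suppressWarnings(as.integer(.edfField(hdr, 252L, 4L)))
  if (any(is.na(c(nHeaderBytes, nRecords, recDur, ns))) || ns < 1L)
    stop("unreadable EDF header in ", path)
  if (ns < 2L) stop("need at least 2 channels, EDF has ", ns)
  sig <- readBin(con, "raw", 256L * ns)
  fld <- function(off, len) {
    vapply(seq_len(ns) - 1L,
           function(i) .edfField(sig, off * ns + i * len, len), "")
  }
  labels <- fld(0L, 16L)
  physMin <- as.numeric(fld(104L, 8L))
  physMax <- as.numeric(fld(112L, 8L))
  digMin <- as.numeric(fld(120L, 8L))
  digMax <- as.numeric(fld(128L, 8L))
  spr <- as.integer(fld(216L, 8L))
  if (any(is.na(spr)) || any(spr < 1L))
    stop("unreadable EDF signal headers in ", path)
  if (length(unique(spr)) != 1L)
    stop("ragged EDF: signals have different samples per record (",
         paste(spr, collapse = ", "), ")")
  if (any(labels == "EDF Annotations"))
    stop("EDF annotation channels are not supported")
  if (recDur <= 0) stop("non-positive record duration in ", path)
  fs <- spr[1L] / recDur
  nPerRec <- sum(spr)
  raw <- readBin(con, "integer", n = nRecords * nPerRec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nRecords * nPerRec)
    stop("unreadable EDF: truncated data records in ", path)
  data <- matrix(0, ns, nRecords * spr[1L])
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    block <- raw[((r - 1L) * nPerRec + 1L):(r * nPerRec)]
    for (i in seq_len(ns)) {
      seg <- block[((i - 1L) * spr[1L] + 1L):(i * spr[1L])]
      data[i, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (seg - digMin[i]) * gain[i] + physMin[i]
    }
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  new("EEGRecording", subjectId = subjectId, data = data, fs = fs,
      channelLabels = labels, band = "time")
}
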