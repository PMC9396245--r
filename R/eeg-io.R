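#' Load a multichannel EEG recording
#'
#' Reads either a plain delimited numeric matrix (channels are rows; the
#' delimiter is auto-detected among comma, tab and whitespace) or an EDF
#' (European Data Format) file. For the matrix format the sampling rate must
#' come from \code{fs} or from a JSON sidecar at \code{<path>.json} with a
#' field \code{"fs"}; for EDF it is taken from the header and all signals
#' must share one sampling rate.
#'
#' @param path input file.
#' @param format \code{"matrix"} or \code{"edf"}.
#' @param fs sampling rate in Hz (matrix format; overrides the sidecar).
#' @param subjectId subject identifier; defaults to the file name without
#'   extension.
#' @param channelLabels optional channel names (matrix format).
#' @return an \code{EEGRecording}.
#' @export
loadRecording <- function(path, format = c("matrix", "edf"), fs = NULL,
                          subjectId = NULL,
                          channelLabels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "edf") return(.readEDF(path, subjectId))
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      sidecar <- file.path(dirname(path),
                           paste0(sub("\\.[^.]*$", "", basename(path)),
                                  ".json"))
    if (!file.exists(sidecar))
      stop("matrix format needs fs= or a JSON sidecar with a 'fs' field")
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(meta$fs)) stop("sidecar ", sidecar, " has no 'fs' field")
    fs <- as.numeric(meta$fs)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("need at least 2 channels in ", path)
  sep <- if (grepl(",", lines[1L])) "," else if (grepl("\t", lines[1L]))
    "\t" else ""
  rows <- lapply(lines, function(ln) {
    fields <- if (sep == "") strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      else strsplit(ln, sep, fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("non-numeric cell in ", path, ": '",
           fields[which(is.na(vals))[1L]], "'")
    vals
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged matrix in ", path, ": rows have differing lengths")
  data <- do.call(rbind, rows)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  new("EEGRecording", subjectId = subjectId, data = data, fs = fs,
      channelLabels = channelLabels, band = "time")
}

#' Write a recording in the delimited matrix format
#'
#' Comma-separated channels-by-samples matrix plus a JSON sidecar
#' \code{<path>.json} holding the sampling rate and channel labels; the files
#' round-trip through \code{loadRecording(format = "matrix")}.
#'
#' @param rec an \code{EEGRecording}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  utils::write.table(rec@data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = rec@fs, subject_id = rec@subjectId,
                            channel_labels = rec@channelLabels,
                            band = rec@band),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subject manifest
#'
#' CSV with columns \code{subject_id}, \code{path}, \code{label} where label
#' is \code{MDD} or \code{NC}. Relative paths are resolved against the
#' manifest's directory. Returns the manifest data.frame with an added
#' numeric \code{y} column (MDD = -1, NC = +1), the label convention used
#' throughout.
#'
#' @param path manifest CSV.
#' @return data.frame with columns subject_id, path, label, y.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(man$label %in% c("MDD", "NC")))
    stop("labels must be 'MDD' or 'NC'")
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man$y <- ifelse(man$label == "MDD", -1, 1)
  man
}
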