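#' @include AllClasses.R
NULL

#' Accessors for hobfn containers
#'
#' Small accessor generics: \code{subjectId} returns the subject identifier,
#' \code{nChannels}/\code{nSamples} the data dimensions, \code{samplingRate}
#' the sampling rate in Hz, \code{bandName} the band tag, \code{fcMethod} the
#' connectivity estimator, \code{seriesMatrix} the underlying numeric series
#' matrix, \code{pairIndexOf} the canonical pair index, and
#' \code{clusterLabels} the per-pair cluster ids.
#'
#' @param x a hobfn object.
#' @return the accessed component.
#' @name accessors
#' @aliases subjectId nChannels nSamples samplingRate bandName fcMethod
#'   seriesMatrix pairIndexOf clusterLabels
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))
#' @rdname accessors
#' @export
setGeneric("fcMethod", function(x) standardGeneric("fcMethod"))
#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))
#' @rdname accessors
#' @export
setGeneric("pairIndexOf", function(x) standardGeneric("pairIndexOf"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "PhaseSeries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "DynamicFC", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "FCSeriesMatrix", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "ClusterMeanSeries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "HOBFNMatrix", function(x) x@subjectId)

#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "PhaseSeries", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "DynamicFC", function(x) dim(x@tensor)[2L])
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nSamples", "PhaseSeries", function(x) ncol(x@data))
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "PhaseSeries", function(x) x@fs)
#' @rdname accessors
setMethod("bandName", "EEGRecording", function(x) x@band)
#' @rdname accessors
setMethod("bandName", "DynamicFC", function(x) x@band)
#' @rdname accessors
setMethod("bandName", "FCSeriesMatrix", function(x) x@band)
#' @rdname accessors
setMethod("fcMethod", "DynamicFC", function(x) x@method)
#' @rdname accessors
setMethod("fcMethod", "FCSeriesMatrix", function(x) x@method)
#' @rdname accessors
setMethod("seriesMatrix", "FCSeriesMatrix", function(x) x@series)
#' @rdname accessors
setMethod("seriesMatrix", "GroupSeriesStack", function(x) x@series)
#' @rdname accessors
setMethod("seriesMatrix", "ClusterMeanSeries", function(x) x@series)
#' @rdname accessors
setMethod("pairIndexOf", "FCSeriesMatrix", function(x) x@pairs)
#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @describeIn accessors number of windows in a DynamicFC
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
setMethod("nWindows", "DynamicFC", function(x) dim(x@tensor)[1L])
#' @rdname accessors
setMethod("nWindows", "FCSeriesMatrix", function(x) ncol(x@series))
#' @rdname accessors
setMethod("nWindows", "WindowPlan", function(x) x@H)

#' Coerce a HOBFNMatrix to its plain matrix
#' @param x a \code{HOBFNMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "HOBFNMatrix", function(x, ...) x@mat)

#' Metrics as a one-row data.frame (percent scale)
#' @param x an \code{EvalMetrics} object.
#' @return data.frame with columns ACC, TPR, TNR, PPV, NPV, F1, TP, FP, TN, FN.
#' @export
metricsTable <- function(x) {
  stopifnot(is(x, "EvalMetrics"))
  data.frame(ACC = x@acc, TPR = x@tpr, TNR = x@tnr, PPV = x@ppv,
             NPV = x@npv, F1 = x@f1, TP = x@tp, FP = x@fp, TN = x@tn,
             FN = x@fn)
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz, band=%s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs, object@band))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf("PhaseSeries '%s': %d channels x %d samples @ %g Hz\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs))
})

setMethod("show", "WindowPlan", function(object) {
  cat(sprintf("WindowPlan: M=%d, W=%d, s=%d -> H=%d windows\n",
              object@M, object@W, object@s, object@H))
})

setMethod("show", "DynamicFC", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("DynamicFC '%s' (%s, band=%s): %d windows x %d x %d\n",
              object@subjectId, object@method, object@band, d[1L], d[2L],
              d[3L]))
})

setMethod("show", "FCSeriesMatrix", function(object) {
  cat(sprintf("FCSeriesMatrix '%s' (%s, band=%s): %d pairs x %d windows\n",
              object@subjectId, object@method, object@band,
              nrow(object@series), ncol(object@series)))
})

setMethod("show", "GroupSeriesStack", function(object) {
  cat(sprintf("GroupSeriesStack: %d pairs x (%d subjects * %d windows)\n",
              nrow(object@series), length(object@subjectIds), object@H))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d pairs -> k=%d clusters (%s), fitted on %d subjects\n",
              length(object@labels), object@k, object@linkage,
              length(object@fittedOn)))
})

setMethod("show", "HOBFNMatrix", function(object) {
  cat(sprintf("HOBFNMatrix '%s': %d x %d clustered high-order network\n",
              object@subjectId, nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet (%s-order): %d subjects x %d features\n",
              object@kind, nrow(object@X), ncol(object@X)))
})

setMethod("show", "EvalMetrics", function(object) {
  cat("EvalMetrics (positive class = MDD):\n")
  print(round(metricsTable(object), 2), row.names = FALSE)
})

setMethod("show", "CVConfig", function(object) {
  cat(sprintf(paste0("CVConfig: %d outer x %d inner folds, %d repeats, seed=%d\n",
                     "  k in {%s}, p in {%s}, lambda in {%s}, c in {%s}, %s clustering\n"),
              object@outerFolds, object@innerFolds, object@repeats,
              object@seed, paste(object@kGrid, collapse = ","),
              paste(object@pGrid, collapse = ","),
              paste(object@lambdaGrid, collapse = ","),
              paste(signif(object@cGrid, 3), collapse = ","),
              if (object@paperFaithful) "all-subject" else "training-only"))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d+%d subjects, E=%d, fs=%g Hz, %gs, G=%d ",
                     "modules, segLen=%d, noiseSd=%g, delta=%g, seed=%d\n"),
              object@RPerGroup, object@RPerGroup, object@E, object@fs,
              object@duration, object@G, object@segLen, object@noiseSd,
              object@delta, object@seed))
})
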