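#' Full high-order network ("correlation's correlation")
#'
#' Entry (r, r') is the Pearson correlation between the connectivity time
#' series of channel pairs r and r': the high-order coupling among up to four
#' channels. The full P x P matrix grows quadratically in the pair count and
#' is retained for small problems and as the reference that the clustered
#' construction must reproduce under singleton clustering; production use
#' goes through \code{clusterPairs} + \code{hofcClustered}.
#'
#' @param series an \code{FCSeriesMatrix} with H >= 3 windows.
#' @return symmetric P x P matrix with unit diagonal; zero-variance series
#'   rows yield 0 entries with a warning.
#' @export
hofcFull <- function(series) {
  stopifnot(is(series, "FCSeriesMatrix"))
  if (ncol(series@series) < 3L)
    stop("need at least 3 windows to correlate connectivity series")
  .safeCorRows(series@series)
}

#' Stack per-pair series across subjects into long vectors
#'
#' Concatenates, for each channel pair, the connectivity time series of all
#' subjects (ascending input order) into one long row vector. Clustering
#' these long vectors gives a single pair-to-cluster assignment shared by
#' every subject.
#'
#' @param seriesList list of \code{FCSeriesMatrix}, one per subject, with
#'   identical pair structure and window count.
#' @return a \code{GroupSeriesStack}.
#' @export
stackLongVectors <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L,
            all(vapply(seriesList, is, TRUE, "FCSeriesMatrix")))
  P <- nrow(seriesList[[1L]]@series)
  H <- ncol(seriesList[[1L]]@series)
  for (s in seriesList) {
    if (nrow(s@series) != P || ncol(s@series) != H)
      stop("all subjects must share the same pair count and window count")
  }
  stack <- do.call(cbind, lapply(seriesList, slot, "series"))
  new("GroupSeriesStack", series = stack,
      subjectIds = vapply(seriesList, slot, "", "subjectId"),
      H = as.integer(H), pairs = seriesList[[1L]]@pairs)
}

#' Cluster connectivity time series
#'
#' Agglomerative hierarchical clustering of the cross-subject long vectors
#' (Ward linkage via \code{hclust(method = "ward.D2")} on Euclidean
#' distances, the natural choice when clusters are represented by their
#' means), cut into k clusters. Deterministic given the input.
#'
#' @param stack a \code{GroupSeriesStack}.
#' @param k number of clusters, 1 <= k <= P.
#' @return a \code{ClusterAssignment}; \code{fittedOn} records the subjects
#'   whose long vectors entered the tree.
#' @export
clusterPairs <- function(stack, k) {
  stopifnot(is(stack, "GroupSeriesStack"))
  P <- nrow(stack@series)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > P)
    stop("k must be in 1..", P)
  tree <- .clusterTree(stack)
  new("ClusterAssignment", labels = .cutTree(tree, k), k = k,
      linkage = "ward.D2/euclidean", fittedOn = stack@subjectIds)
}

# Tree and cut split out so nested CV can fit one tree per training set and
# cut it at every k in the grid.
.clusterTree <- function(stack) {
  P <- nrow(stack@series)
  if (P < 2L) return(NULL)
  stats::hclust(stats::dist(stack@series, method = "euclidean"),
                method = "ward.D2")
}

.cutTree <- function(tree, k) {
  if (is.null(tree)) return(rep(1L, 1L))
  as.integer(stats::cutree(tree, k = k))
}

#' Per-cluster mean connectivity series
#'
#' For one subject, averages the connectivity time series of all pairs
#' assigned to each cluster: row g of the result is the arithmetic mean of
#' the member-pair rows over the subject's own windows.
#'
#' @param series the subject's \code{FCSeriesMatrix}.
#' @param assign a \code{ClusterAssignment} over the same pairs.
#' @return a \code{ClusterMeanSeries} (k x H).
#' @export
clusterMeanSeries <- function(series, assign) {
  stopifnot(is(series, "FCSeriesMatrix"), is(assign, "ClusterAssignment"))
  if (length(assign@labels) != nrow(series@series))
    stop("assignment covers ", length(assign@labels), " pairs but series has ",
         nrow(series@series))
  means <- rowsum(series@series, assign@labels) /
    as.vector(table(factor(assign@labels, levels = seq_len(assign@k))))
  dimnames(means) <- NULL
  new("ClusterMeanSeries", subjectId = series@subjectId, series = means)
}

#' Clustered high-order network
#'
#' The k x k matrix of Pearson correlations between cluster-mean
#' connectivity series: a small high-order network whose vertices are pair
#' clusters. With singleton clusters (k = P) it reduces exactly to
#' \code{hofcFull}.
#'
#' @param means a \code{ClusterMeanSeries} with k >= 2 and H >= 3.
#' @return a \code{HOBFNMatrix}; zero-variance mean series give 0 entries
#'   with a warning.
#' @export
hofcClustered <- function(means) {
  stopifnot(is(means, "ClusterMeanSeries"))
  if (nrow(means@series) < 2L) stop("need at least 2 clusters")
  if (ncol(means@series) < 3L)
    stop("need at least 3 windows to correlate cluster-mean series")
  new("HOBFNMatrix", subjectId = means@subjectId,
      mat = .safeCorRows(means@series))
}
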