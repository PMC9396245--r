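#' Canonical channel-pair index
#'
#' All vectorizations of symmetric channel-by-channel matrices in the package
#' use the same canonical order: unordered pairs (i, j) with i < j, sorted
#' lexicographically, giving P = E(E-1)/2 pairs. Row r of the returned matrix
#' is the r-th pair.
#'
#' @param E number of channels (>= 2).
#' @return integer matrix P x 2 with columns \code{i} and \code{j}.
#' @examples
#' pairIndex(3)  # (1,2), (1,3), (2,3)
#' @export
pairIndex <- function(E) {
  E <- as.integer(E)
  stopifnot(E >= 2L)
  idx <- t(utils::combn(E, 2L))
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j")
  idx
}

# Vectorize the upper triangle of a symmetric matrix in canonical pair order.
.upperVec <- function(M, pairs = pairIndex(nrow(M))) {
  M[pairs]
}

# Rebuild a symmetric matrix (given diagonal value) from its canonical vector.
.symFromVec <- function(v, E, diagVal, pairs = pairIndex(E)) {
  M <- matrix(diagVal * 0, E, E)
  M[pairs] <- v
  M <- M + t(M)
  diag(M) <- diagVal
  M
}

# Row-wise Pearson correlation with zero-variance rows mapped to 0 (warning),
# unit diagonal, exact symmetry.
.safeCorRows <- function(A) {
  n <- nrow(A)
  sds <- apply(A, 1L, stats::sd)
  zv <- sds == 0 | !is.finite(sds)
  C <- matrix(0, n, n)
  ok <- which(!zv)
  if (length(ok) >= 2L)
    C[ok, ok] <- stats::cor(t(A[ok, , drop = FALSE]))
  if (any(zv))
    warning("zero-variance series: correlations involving ",
            sum(zv), " row(s) set to 0")
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C
}

# Column standardizer fitted on training data; zero-variance columns are
# recorded and excluded from the transformed matrix.
.standardizeFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  keep <- which(scl > 0 & is.finite(scl))
  list(center = ctr, scale = scl, keep = keep)
}

.standardizeApply <- function(st, X) {
  Xs <- sweep(X[, st$keep, drop = FALSE], 2L, st$center[st$keep], "-")
  sweep(Xs, 2L, st$scale[st$keep], "/")
}

# Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}
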