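# Independent oracles used by the tests. These deliberately avoid the code
# paths of the implementation they check.

# Element-by-element Pearson correlation between all row pairs (double loop).
oracleRowCor <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- stats::cor(A[i, ], A[j, ])
    }
  }
  out
}

# LASSO objective: 1/2 * RSS + lambda * L1, on given (standardized) data.
lassoObjective <- function(alpha, X, y, lambda) {
  0.5 * sum((y - X %*% alpha)^2) + lambda * sum(abs(alpha))
}

# Exhaustive grid minimizer of the 2-feature LASSO objective.
lassoGridOracle <- function(X, y, lambda, lim = 3, step = 0.002) {
  g <- seq(-lim, lim, by = step)
  best <- c(obj = Inf, a1 = 0, a2 = 0)
  x1 <- X[, 1L]
  x2 <- X[, 2L]
  for (a1 in g) {
    r1 <- y - x1 * a1
    # vectorized over a2
    rss <- colSums((matrix(r1, length(y), length(g)) - outer(x2, g))^2)
    obj <- 0.5 * rss + lambda * (abs(a1) + abs(g))
    k <- which.min(obj)
    if (obj[k] < best["obj"]) best <- c(obj = obj[k], a1 = a1, a2 = g[k])
  }
  best
}

# Hard-margin linear SVM for a small separable set by KKT active-set
# enumeration: minimize 1/2 ||w||^2 s.t. y_i (w.x_i + b) >= 1. Enumerates
# candidate support sets, solves the equality-constrained KKT system and
# keeps the feasible solution with nonnegative multipliers.
svmQPOracle <- function(X, y) {
  n <- nrow(X)
  best <- NULL
  for (size in 2:n) {
    for (S in utils::combn(n, size, simplify = FALSE)) {
      if (length(unique(y[S])) < 2L) next
      Xs <- X[S, , drop = FALSE]
      ys <- y[S]
      # KKT: w = sum a_i y_i x_i ; sum a_i y_i = 0 ; y_i (w.x_i + b) = 1
      K <- (Xs %*% t(Xs)) * outer(ys, ys)
      A <- rbind(cbind(K, ys), c(ys, 0))
      rhs <- c(rep(1, length(S)), 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a <- sol[seq_along(S)]
      b <- sol[length(sol)]
      if (any(a < -1e-9)) next
      w <- drop(t(Xs) %*% (a * ys))
      if (any(y * (X %*% w + b) < 1 - 1e-7)) next
      if (is.null(best) || sum(w^2) < best$norm2 - 1e-12)
        best <- list(w = w, b = b, norm2 = sum(w^2))
    }
  }
  best
}

# Best 2-partition of rows by within-cluster sum of squares (exhaustive).
bestTwoPartition <- function(A) {
  n <- nrow(A)
  wss <- function(B) if (nrow(B) <= 1L) 0 else
    sum(sweep(B, 2L, colMeans(B))^2)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    g <- c(0L, as.integer(intToBits(code)[1:(n - 1)]))
    s <- wss(A[g == 0L, , drop = FALSE]) + wss(A[g == 1L, , drop = FALSE])
    if (is.null(best) || s < best$wss) best <- list(labels = g, wss = s)
  }
  best$labels
}

# Construct a sample with exactly the requested mean and SD.
sampleWithSummary <- function(n, m, s) {
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}
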