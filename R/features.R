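#' Low-order feature vector
#'
#' Element-wise mean of the H window matrices (equivalently the row means of
#' the per-pair connectivity series), vectorized in canonical pair order.
#' Averaging over windows removes the phase mismatch of window dynamics
#' across subjects; no per-window dynamic low-order features are exposed.
#'
#' @param x a \code{DynamicFC} or \code{FCSeriesMatrix}.
#' @return numeric vector of length P.
#' @export
lowOrderFeature <- function(x) {
  if (is(x, "DynamicFC")) x <- toSeries(x)
  stopifnot(is(x, "FCSeriesMatrix"))
  rowMeans(x@series)
}

#' High-order feature vector
#'
#' Upper triangle of the clustered high-order network in canonical pair
#' order (length k(k-1)/2).
#'
#' @param hob a \code{HOBFNMatrix} (or plain symmetric matrix).
#' @return numeric vector.
#' @export
highOrderFeature <- function(hob) {
  M <- if (is(hob, "HOBFNMatrix")) hob@mat else hob
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) >= 2L)
  .upperVec(M)
}

# Vectorized two-sample t-tests across feature columns.
.colTTest <- function(X, y, welch = FALSE) {
  g1 <- y < 0
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[g2, , drop = FALSE], 2L, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, p = p, degenerate = !is.finite(tt))
}

#' t-test feature screen
#'
#' Per-feature two-sample two-tailed t-test between the two label groups on
#' training data; features with p below the threshold are kept. Features
#' with zero pooled variance (constant within both groups) have no defined
#' statistic and are dropped. Pooled-variance Student's t is the default;
#' Welch's correction is available via \code{welch = TRUE}.
#'
#' @param X numeric training matrix, subjects x features.
#' @param y labels, -1 (MDD) / +1 (NC), both classes with >= 2 subjects.
#' @param pThresh significance level.
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @param subjectIds training subject ids recorded in the audit field.
#' @return a \code{SelectionMask} (stage "ttest") whose \code{detail} holds
#'   the per-feature p-values.
#' @export
ttestFilter <- function(X, y, pThresh, welch = FALSE,
                        subjectIds = rownames(X) %||% character()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (sum(y < 0) < 2L || sum(y > 0) < 2L)
    stop("need at least 2 subjects per class")
  tt <- .colTTest(X, y, welch = welch)
  kept <- which(!tt$degenerate & tt$p < pThresh)
  new("SelectionMask", stage = "ttest", kept = as.integer(kept),
      fittedOn = as.character(subjectIds),
      detail = list(p = tt$p, t = tt$t, pThresh = pThresh, welch = welch))
}

#' LASSO feature selection
#'
#' Minimizes 1/2 * sum_l (y_l - <x_l, alpha>)^2 + lambda * ||alpha||_1 with
#' no intercept; columns are standardized internally on the training data
#' (mean 0, unit SD) and y is centered, which makes the intercept-free model
#' well-posed for the +/-1 labels. Features with nonzero weight
#' (|alpha| > 1e-10) are kept. Solved by coordinate descent (glmnet) except
#' in the exactly solvable limits (lambda = 0: least squares; one column:
#' closed-form soft threshold).
#'
#' @param X numeric training matrix (typically already screened by
#'   \code{ttestFilter}).
#' @param y labels -1/+1.
#' @param lambda regularization parameter, >= 0, on the un-normalized
#'   1/2-residual-sum-of-squares scale.
#' @param subjectIds training subject ids for the audit field.
#' @return a \code{SelectionMask} (stage "lasso") whose \code{detail$alpha}
#'   holds the weights on the standardized scale.
#' @export
lassoSelect <- function(X, y, lambda,
                        subjectIds = rownames(X) %||% character()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single number >= 0")
  n <- nrow(X)
  st <- .standardizeFit(X)
  alpha <- numeric(ncol(X))
  if (length(st$keep) > 0L) {
    Xs <- .standardizeApply(st, X)
    yc <- y - mean(y)
    if (lambda == 0) {
      a <- stats::lm.fit(Xs, yc)$coefficients
      a[is.na(a)] <- 0
    } else if (ncol(Xs) == 1L) {
      rho <- sum(Xs[, 1L] * yc)
      a <- sign(rho) * max(abs(rho) - lambda, 0) / sum(Xs[, 1L]^2)
    } else {
      fit <- glmnet::glmnet(Xs, yc, alpha = 1, lambda = lambda / n,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-12, maxit = 1e6)
      a <- as.numeric(fit$beta)
    }
    alpha[st$keep] <- a
  }
  kept <- which(abs(alpha) > 1e-10)
  new("SelectionMask", stage = "lasso", kept = as.integer(kept),
      fittedOn = as.character(subjectIds),
      detail = list(alpha = alpha, lambda = lambda))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction, p-value from the
#' chi-square distribution with 1 degree of freedom. Used for cohort
#' count comparisons such as sex by diagnosis.
#'
#' @param table 2x2 matrix of nonnegative counts with positive marginals.
#' @return list with \code{statistic} and \code{p}.
#' @examples
#' chi2Test2x2(rbind(c(12, 12), c(20, 9)))  # p ~= 0.16
#' @export
chi2Test2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive")
  expect <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - expect)^2 / expect)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample two-tailed t-test computed from group sizes,
#' means and standard deviations, for reproducing cohort tables that report
#' only summaries.
#'
#' @param n1,mean1,sd1 first group: size (>= 2), mean, SD.
#' @param n2,mean2,sd2 second group.
#' @param welch use Welch's t instead of the pooled-variance form.
#' @return list with \code{t}, \code{df} and \code{p}.
#' @examples
#' tFromSummary(24, 18.3, 7.3, 29, 2.6, 2.6)$p  # ~1e-14
#' @export
tFromSummary <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero; t is undefined")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tt <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}
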