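#' Train a linear soft-margin SVM
#'
#' Hinge-loss linear support-vector machine (libsvm via e1071) with cost
#' parameter c; inputs are used as-is (no internal rescaling, the pipeline
#' standardizes features on training data beforehand). The returned model
#' stores the explicit primal weights, with the orientation normalized so
#' that a positive decision score predicts the +1 (NC) class.
#'
#' @param X numeric training matrix, subjects x features.
#' @param y labels -1 (MDD) / +1 (NC); both classes must be present.
#' @param cost soft-margin cost c > 0.
#' @return a \code{LinearSVMModel}.
#' @export
trainLinearSVM <- function(X, y, cost) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), cost > 0)
  if (length(unique(sign(y))) < 2L)
    stop("both classes must be present in the training labels")
  yf <- factor(y, levels = c(-1, 1))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  pred <- as.numeric(as.character(stats::predict(fit, X)))
  sc <- drop(X %*% w + b)
  agree <- sum(sign(sc) == pred & sc != 0)
  disagree <- sum(sign(sc) == -pred & sc != 0)
  if (disagree > agree) {
    w <- -w
    b <- -b
  }
  new("LinearSVMModel", w = as.numeric(w), b = as.numeric(b),
      cost = as.numeric(cost))
}

#' Raw decision scores of a linear SVM
#'
#' d(x) = <w, x> + b, with no thresholding or calibration: these raw scores
#' are what the fusion stage combines.
#'
#' @param model a \code{LinearSVMModel}.
#' @param X numeric matrix with one row per observation.
#' @return numeric score vector.
#' @export
decisionScores <- function(model, X) {
  stopifnot(is(model, "LinearSVMModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@w))
    stop("feature dimension ", ncol(X), " does not match the model (",
         length(model@w), ")")
  drop(X %*% model@w + model@b)
}

#' Enumerate fusion weight tuples
#'
#' All tuples (beta_1, ..., beta_F) with every beta_f drawn from the grid
#' {0.1, 0.2, ..., 0.9} and sum(beta) = 1, in lexicographic order. F = 1
#' degenerates to the single classifier, beta = (1).
#'
#' @param F number of classifiers to fuse.
#' @return list of numeric weight vectors.
#' @examples
#' length(enumerateFusionWeights(2))  # 9
#' length(enumerateFusionWeights(3))  # 36
#' @export
enumerateFusionWeights <- function(F) {
  F <- as.integer(F)
  stopifnot(F >= 1L)
  if (F == 1L) return(list(1))
  # compositions of 10 tenths into F parts, each part in 1..9
  rec <- function(parts, left) {
    nLeft <- F - length(parts)
    if (nLeft == 0L)
      return(if (left == 0L) list(parts) else list())
    out <- list()
    for (v in 1:9) {
      rest <- left - v
      if (rest >= nLeft - 1L && rest <= 9L * (nLeft - 1L))
        out <- c(out, rec(c(parts, v), rest))
    }
    out
  }
  tuples <- rec(integer(), 10L)
  if (length(tuples) == 0L)
    stop("no weight tuple on the 0.1..0.9 grid sums to 1 for F = ", F)
  lapply(tuples, function(t) t / 10)
}

#' Fuse decision scores
#'
#' Weighted linear combination of per-classifier decision scores,
#' fused = sum_f beta_f * d_f(x); the predicted label is -1 (MDD) when the
#' fused score is negative, +1 (NC) when positive, and +1 on an exact tie
#' (documented tie rule).
#'
#' @param scoreLists list of equal-length numeric score vectors.
#' @param beta numeric weight vector, one weight per score list.
#' @return list with \code{fused} scores and \code{pred} labels.
#' @export
fuse <- function(scoreLists, beta) {
  stopifnot(is.list(scoreLists), length(scoreLists) == length(beta))
  n <- unique(lengths(scoreLists))
  if (length(n) != 1L) stop("score lists must have equal length")
  fused <- numeric(n)
  for (f in seq_along(beta)) fused <- fused + beta[f] * scoreLists[[f]]
  list(fused = fused, pred = ifelse(fused < 0, -1, 1))
}

#' Classification metrics with MDD as the positive class
#'
#' Confusion counts and the six summary metrics (percent): accuracy,
#' sensitivity/TPR, specificity/TNR, precision/PPV, NPV and F1
#' (= 2*PPV*TPR/(PPV+TPR)). The depressed group (label -1) is the positive
#' class. Ratios with a zero denominator are NaN and raise a warning.
#'
#' @param yTrue,yPred label vectors in {-1, +1}.
#' @return an \code{EvalMetrics}.
#' @examples
#' # TP=10, FN=2, TN=8, FP=4 -> ACC 75.00, F1 76.92
#' m <- computeMetrics(c(rep(-1, 12), rep(1, 12)),
#'                     c(rep(-1, 10), rep(1, 2), rep(-1, 4), rep(1, 8)))
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L)
    stop("yTrue and yPred must be non-empty and of equal length")
  tp <- sum(yTrue == -1 & yPred == -1)
  fn <- sum(yTrue == -1 & yPred == 1)
  tn <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 1 & yPred == -1)
  rat <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    100 * num / den
  }
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  tpr <- rat(tp, tp + fn, "TPR")
  tnr <- rat(tn, tn + fp, "TNR")
  ppv <- rat(tp, tp + fp, "PPV")
  npv <- rat(tn, tn + fn, "NPV")
  f1 <- if (is.finite(ppv) && is.finite(tpr) && (ppv + tpr) > 0)
    2 * ppv * tpr / (ppv + tpr) else NaN
  new("EvalMetrics", tp = tp, fp = fp, tn = tn, fn = fn, acc = acc,
      tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, f1 = f1)
}
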