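#' Nested cross-validation configuration
#'
#' \code{cvConfig} builds a \code{CVConfig}; defaults follow the full study
#' protocol (nested ten-fold CV repeated 10 times; k in 100..800 by 100,
#' p in 0.01..0.05 by 0.01, lambda in 0.1..0.9 by 0.1, c in 2^-4..2^4).
#' \code{synthCVConfig} is the desk-scale configuration used for the
#' synthetic validation study: grids reduced to the ranges that matter at
#' P = 66 pairs (k in {3, 4, 6}, p = 0.05, lambda in {0.1, 0.5}, c = 1),
#' five inner folds and five repeats, chosen once for the synthetic study
#' conditions.
#'
#' @param outerFolds,innerFolds,repeats fold structure.
#' @param seed integer seed for all partitions.
#' @param kGrid,pGrid,lambdaGrid,cGrid hyper-parameter grids; kGrid is
#'   clipped to the pair count at fit time so small problems remain runnable.
#' @param paperFaithful cluster on all subjects' long vectors (the original
#'   all-subject protocol, which lets test subjects influence the clustering)
#'   instead of training subjects only.
#' @return a \code{CVConfig}.
#' @export
cvConfig <- function(outerFolds = 10, innerFolds = 10, repeats = 10,
                     seed = 1, kGrid = seq(100, 800, by = 100),
                     pGrid = seq(0.01, 0.05, by = 0.01),
                     lambdaGrid = seq(0.1, 0.9, by = 0.1),
                     cGrid = 2^(-4:4), paperFaithful = FALSE) {
  new("CVConfig", outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds), repeats = as.integer(repeats),
      seed = as.integer(seed), kGrid = as.numeric(kGrid),
      pGrid = as.numeric(pGrid), lambdaGrid = as.numeric(lambdaGrid),
      cGrid = as.numeric(cGrid), paperFaithful = isTRUE(paperFaithful))
}

#' @rdname cvConfig
#' @export
synthCVConfig <- function(seed = 1, repeats = 5, paperFaithful = FALSE) {
  cvConfig(outerFolds = 10, innerFolds = 5, repeats = repeats, seed = seed,
           kGrid = c(3, 4, 6), pGrid = 0.05, lambdaGrid = c(0.1, 0.5),
           cGrid = 1, paperFaithful = paperFaithful)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cls in c(-1, 1)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

# Fit the t-test -> LASSO -> SVM chain for one feature block on training
# data. If the t-test keeps nothing, the single smallest-p feature is kept;
# if the LASSO zeroes everything, the t-test set is used (still a subset of
# the t-test mask). Both guards keep desk-scale folds total and are
# deterministic.
.fitChain <- function(X, y, subjects, p, lam, cost) {
  st <- .standardizeFit(X)
  if (length(st$keep) == 0L)
    stop("no feature with positive variance in the training set")
  Xs <- .standardizeApply(st, X)
  tm <- ttestFilter(Xs, y, p, subjectIds = subjects)
  tkeep <- tm@kept
  if (length(tkeep) == 0L)
    tkeep <- which.min(tm@detail$p)
  lm <- lassoSelect(Xs[, tkeep, drop = FALSE], y, lam,
                    subjectIds = subjects)
  lkeep <- tkeep[lm@kept]
  if (length(lkeep) == 0L) lkeep <- tkeep
  stl <- .standardizeFit(Xs[, lkeep, drop = FALSE])
  Xf <- .standardizeApply(stl, Xs[, lkeep, drop = FALSE])
  model <- trainLinearSVM(Xf, y, cost)
  list(st = st, tkeep = tkeep, lkeep = lkeep, stl = stl, model = model,
       keptOriginal = st$keep[lkeep], fittedOn = subjects)
}

.predictChain <- function(chain, X) {
  Xs <- .standardizeApply(chain$st, X)
  Xf <- .standardizeApply(chain$stl, Xs[, chain$lkeep, drop = FALSE])
  decisionScores(chain$model, Xf)
}

# Build the HO feature matrix (subjects x k(k-1)/2) for a given assignment.
.hoFeatures <- function(seriesList, assign) {
  d <- assign@k * (assign@k - 1L) / 2L
  out <- vapply(seriesList, function(s) {
    highOrderFeature(suppressWarnings(hofcClustered(clusterMeanSeries(s, assign))))
  }, numeric(d))
  t(matrix(out, nrow = d))
}

# Fit LO+HO classifiers for every network on a training subject set.
# loAll: per-network precomputed full LO feature matrices (all subjects).
# trees are cached per (network, training-set) by the caller.
.fitAllNetworks <- function(networks, loAll, trees, subjects, trainIdx, y,
                            k, p, lam, cost) {
  chains <- list()
  hoFeat <- list()
  for (nm in names(networks)) {
    seriesList <- networks[[nm]]
    P <- nrow(seriesList[[1L]]@series)
    kUse <- as.integer(min(k, P))
    labels <- .cutTree(trees[[nm]], kUse)
    assign <- new("ClusterAssignment", labels = labels, k = kUse,
                  linkage = "ward.D2/euclidean",
                  fittedOn = subjects[trainIdx])
    hoX <- .hoFeatures(seriesList, assign)
    hoFeat[[nm]] <- hoX
    chains[[paste0(nm, ".LO")]] <-
      .fitChain(loAll[[nm]][trainIdx, , drop = FALSE], y[trainIdx],
                subjects[trainIdx], p, lam, cost)
    chains[[paste0(nm, ".HO")]] <-
      .fitChain(hoX[trainIdx, , drop = FALSE], y[trainIdx],
                subjects[trainIdx], p, lam, cost)
  }
  list(chains = chains, hoFeat = hoFeat, k = k)
}

.scoreAllNetworks <- function(fit, networks, loAll, idx) {
  out <- list()
  for (nm in names(networks)) {
    out[[paste0(nm, ".LO")]] <-
      .predictChain(fit$chains[[paste0(nm, ".LO")]],
                    loAll[[nm]][idx, , drop = FALSE])
    out[[paste0(nm, ".HO")]] <-
      .predictChain(fit$chains[[paste0(nm, ".HO")]],
                    fit$hoFeat[[nm]][idx, , drop = FALSE])
  }
  out
}

#' Nested repeated stratified cross-validation
#'
#' Full evaluation protocol: in each of \code{repeats} repetitions the
#' subjects are stratified into \code{outerFolds} outer folds; for every
#' outer fold an inner stratified CV over the hyper-parameter grid
#' (k, p, lambda, c) plus the fusion-weight grid selects, by mean inner
#' fused accuracy, the configuration that is then refitted on the full outer
#' training set and evaluated on the held-out fold. Pair clustering, feature
#' screens, the LASSO, standardization and the SVMs are all fitted on
#' training subjects only (unless \code{paperFaithful}); held-out labels are
#' never touched, and the per-fold \code{fittedOn} audit records this.
#'
#' Fold accuracies are averaged over folds and then repeats; the remaining
#' metrics are computed from the pooled confusion counts of each repeat and
#' averaged over repeats (for equal-size folds the two accuracy conventions
#' coincide).
#'
#' @param networks named list of networks (e.g. one band); each element is a
#'   list of \code{FCSeriesMatrix}, one per subject, all networks over the
#'   same subjects in the same order. Each network contributes a low-order
#'   and a high-order classifier, so F = 2 * length(networks) classifiers
#'   are fused.
#' @param y numeric labels, -1 (MDD) / +1 (NC), one per subject.
#' @param config a \code{CVConfig}.
#' @param subjects subject identifiers; defaults to those of the first
#'   network's series.
#' @return a list of class \code{"bfnCVReport"}: \code{summary} (named list
#'   of \code{EvalMetrics} per classifier and fused, averaged over repeats),
#'   \code{foldAcc} (fused per-fold accuracies), \code{folds} (chosen
#'   hyper-parameters, train/test subjects and audit fields per fold),
#'   \code{selection} (feature-selection counts across all refits),
#'   \code{referenceAssignments} (all-subject clusterings per network and k,
#'   for reporting only) and \code{config}.
#' @export
nestedCV <- function(networks, y, config,
                     subjects = vapply(networks[[1L]], slot, "",
                                       "subjectId")) {
  stopifnot(is.list(networks), length(networks) >= 1L, is(config, "CVConfig"))
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    names(networks) <- paste0("net", seq_along(networks))
  R <- length(y)
  for (nw in networks) stopifnot(length(nw) == R)
  if (sum(y < 0) < 2L || sum(y > 0) < 2L)
    stop("need at least 2 subjects per class")

  loAll <- lapply(networks, function(nw)
    t(vapply(nw, lowOrderFeature, numeric(nrow(nw[[1L]]@series)))))
  Pmin <- min(vapply(networks, function(nw) nrow(nw[[1L]]@series), 0))
  kGrid <- sort(unique(pmin(config@kGrid, Pmin)))
  grid <- expand.grid(k = kGrid, p = config@pGrid,
                      lambda = config@lambdaGrid, c = config@cGrid,
                      KEEP.OUT.ATTRS = FALSE)
  Fn <- 2L * length(networks)
  betas <- enumerateFusionWeights(Fn)
  clsNames <- as.vector(t(outer(names(networks), c("LO", "HO"), paste,
                                sep = ".")))

  treeCache <- new.env(parent = emptyenv())
  getTrees <- function(trainIdx) {
    key <- paste(trainIdx, collapse = ",")
    if (!is.null(treeCache[[key]])) return(treeCache[[key]])
    trees <- lapply(networks, function(nw) {
      idx <- if (config@paperFaithful) seq_len(R) else trainIdx
      .clusterTree(stackLongVectors(nw[idx]))
    })
    treeCache[[key]] <- trees
    trees
  }

  selLO <- lapply(networks, function(nw)
    integer(nrow(nw[[1L]]@series)))
  selHO <- lapply(networks, function(nw) {
    out <- lapply(kGrid, function(k) integer(min(k, Pmin) * (min(k, Pmin) - 1) / 2))
    names(out) <- as.character(kGrid)
    out
  })

  set.seed(config@seed)
  repeatMetrics <- list()
  foldRecords <- list()
  foldAcc <- numeric(0)
  perClsConf <- matrix(0, config@repeats, 4L * (Fn + 1L))

  for (rep_i in seq_len(config@repeats)) {
    outer <- .stratifiedFolds(y, config@outerFolds)
    confFused <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    confCls <- matrix(0, Fn, 4L,
                      dimnames = list(clsNames, c("tp", "fp", "tn", "fn")))
    for (of in seq_len(config@outerFolds)) {
      testIdx <- which(outer == of)
      trainIdx <- which(outer != of)
      if (length(testIdx) == 0L) next
      if (length(unique(sign(y[trainIdx]))) < 2L)
        stop("degenerate outer fold: training set has one class")
      # ---- inner grid search ----
      inner <- .stratifiedFolds(y[trainIdx], config@innerFolds)
      valScores <- array(NA_real_, c(length(trainIdx), Fn, nrow(grid)))
      for (inf in seq_len(config@innerFolds)) {
        vIdx <- which(inner == inf)
        tIdx <- which(inner != inf)
        if (length(vIdx) == 0L) next
        if (length(unique(sign(y[trainIdx][tIdx]))) < 2L) next
        innerTrain <- trainIdx[tIdx]
        trees <- getTrees(innerTrain)
        for (g in seq_len(nrow(grid))) {
          fit <- .fitAllNetworks(networks, loAll, trees, subjects,
                                 innerTrain, y, grid$k[g], grid$p[g],
                                 grid$lambda[g], grid$c[g])
          sc <- .scoreAllNetworks(fit, networks, loAll, trainIdx[vIdx])
          for (f in seq_len(Fn))
            valScores[vIdx, f, g] <- sc[[clsNames[f]]]
        }
      }
      yInner <- y[trainIdx]
      best <- c(acc = -Inf, g = 1L, b = 1L)
      for (g in seq_len(nrow(grid))) {
        have <- which(!is.na(valScores[, 1L, g]))
        if (length(have) == 0L) next
        vs <- matrix(valScores[have, , g], ncol = Fn)
        for (b in seq_along(betas)) {
          fusedScores <- as.numeric(vs %*% betas[[b]])
          acc <- mean(ifelse(fusedScores < 0, -1, 1) == yInner[have])
          if (acc > best["acc"]) best <- c(acc = acc, g = g, b = b)
        }
      }
      g <- as.integer(best["g"]); b <- as.integer(best["b"])
      # ---- refit on the outer training set, evaluate held-out fold ----
      trees <- getTrees(trainIdx)
      fit <- .fitAllNetworks(networks, loAll, trees, subjects, trainIdx, y,
                             grid$k[g], grid$p[g], grid$lambda[g],
                             grid$c[g])
      sc <- .scoreAllNetworks(fit, networks, loAll, testIdx)
      scoreMat <- vapply(clsNames, function(nm) sc[[nm]],
                         numeric(length(testIdx)))
      if (is.null(dim(scoreMat)))
        scoreMat <- matrix(scoreMat, nrow = length(testIdx))
      fused <- fuse(lapply(seq_len(Fn), function(f) scoreMat[, f]),
                    betas[[b]])
      yTest <- y[testIdx]
      foldAcc <- c(foldAcc, 100 * mean(fused$pred == yTest))
      confFused <- confFused + c(
        tp = sum(yTest == -1 & fused$pred == -1),
        fp = sum(yTest == 1 & fused$pred == -1),
        tn = sum(yTest == 1 & fused$pred == 1),
        fn = sum(yTest == -1 & fused$pred == 1))
      for (f in seq_len(Fn)) {
        pf <- ifelse(scoreMat[, f] < 0, -1, 1)
        confCls[f, ] <- confCls[f, ] + c(
          sum(yTest == -1 & pf == -1), sum(yTest == 1 & pf == -1),
          sum(yTest == 1 & pf == 1), sum(yTest == -1 & pf == 1))
      }
      # selection counts + audit
      for (nm in names(networks)) {
        chLO <- fit$chains[[paste0(nm, ".LO")]]
        selLO[[nm]][chLO$keptOriginal] <- selLO[[nm]][chLO$keptOriginal] + 1L
        chHO <- fit$chains[[paste0(nm, ".HO")]]
        kk <- as.character(min(grid$k[g], Pmin))
        if (kk %in% names(selHO[[nm]]))
          selHO[[nm]][[kk]][chHO$keptOriginal] <-
            selHO[[nm]][[kk]][chHO$keptOriginal] + 1L
      }
      foldRecords[[length(foldRecords) + 1L]] <- list(
        repeat_i = rep_i, fold = of,
        train = subjects[trainIdx], test = subjects[testIdx],
        k = grid$k[g], p = grid$p[g], lambda = grid$lambda[g],
        c = grid$c[g], beta = betas[[b]], innerAcc = unname(best["acc"]),
        fittedOn = unique(unlist(lapply(fit$chains, `[[`, "fittedOn"))))
    }
    perClsConf[rep_i, ] <- c(confFused, t(confCls))
  }

  # average metrics over repeats from pooled per-repeat confusions
  avgMetrics <- function(cols) {
    ms <- lapply(seq_len(config@repeats), function(r) {
      v <- perClsConf[r, cols]
      suppressWarnings(computeMetrics(
        c(rep(-1, v[1] + v[4]), rep(1, v[2] + v[3])),
        c(rep(-1, v[1]), rep(1, v[4]), rep(-1, v[2]), rep(1, v[3]))))
    })
    fields <- c("acc", "tpr", "tnr", "ppv", "npv", "f1", "tp", "fp", "tn",
                "fn")
    means <- vapply(fields, function(f)
      mean(vapply(ms, slot, 0, f)), 0)
    means <- unname(means)
    names(means) <- fields
    new("EvalMetrics", tp = unname(means["tp"]), fp = unname(means["fp"]),
        tn = unname(means["tn"]), fn = unname(means["fn"]),
        acc = unname(means["acc"]), tpr = unname(means["tpr"]),
        tnr = unname(means["tnr"]), ppv = unname(means["ppv"]),
        npv = unname(means["npv"]), f1 = unname(means["f1"]))
  }
  summary <- list(fused = avgMetrics(1:4))
  for (f in seq_len(Fn))
    summary[[clsNames[f]]] <- avgMetrics(4L * f + 1:4)

  refAssign <- lapply(names(networks), function(nm) {
    stack <- stackLongVectors(networks[[nm]])
    tree <- .clusterTree(stack)
    out <- lapply(kGrid, function(k)
      new("ClusterAssignment", labels = .cutTree(tree, as.integer(k)),
          k = as.integer(k), linkage = "ward.D2/euclidean",
          fittedOn = subjects))
    names(out) <- as.character(kGrid)
    out
  })
  names(refAssign) <- names(networks)

  structure(list(summary = summary, foldAcc = foldAcc,
                 meanFusedAcc = mean(foldAcc), folds = foldRecords,
                 selection = list(lo = selLO, ho = selHO),
                 referenceAssignments = refAssign,
                 networks = names(networks), subjects = subjects,
                 pairs = lapply(networks, function(nw) nw[[1L]]@pairs),
                 channelLabels = lapply(networks, function(nw)
                   nw[[1L]]@channelLabels),
                 config = config),
            class = "bfnCVReport")
}

#' @export
print.bfnCVReport <- function(x, ...) {
  cat(sprintf("Nested CV report: %d subjects, %d repeats x %d outer folds\n",
              length(x$subjects), x$config@repeats, x$config@outerFolds))
  cat(sprintf("Mean fused fold accuracy: %.2f%%\n", x$meanFusedAcc))
  for (nm in names(x$summary)) {
    cat(nm, ": ")
    m <- metricsTable(x$summary[[nm]])
    cat(sprintf("ACC %.2f TPR %.2f TNR %.2f PPV %.2f NPV %.2f F1 %.2f\n",
                m$ACC, m$TPR, m$TNR, m$PPV, m$NPV, m$F1))
  }
  invisible(x)
}
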