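test_that("linear SVM solves the canonical 1-D max-margin problem", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  m <- trainLinearSVM(X, y, cost = 1e6)
  sc <- decisionScores(m, matrix(c(-1, -0.2, 0.4, 1), 4, 1))
  expect_equal(sign(sc), c(-1, -1, 1, 1))
  expect_equal(sc[c(1, 4)], c(-1, 1), tolerance = 1e-3)
})

test_that("linear SVM agrees with the KKT active-set oracle on 4 points", {
  X <- rbind(c(1, 1), c(2, 0.5), c(-1, -1), c(-2, -0.5))
  y <- c(1, 1, -1, -1)
  m <- trainLinearSVM(X, y, cost = 1e6)
  ref <- svmQPOracle(X, y)
  cosSim <- sum(m@w * ref$w) / sqrt(sum(m@w^2) * sum(ref$w^2))
  expect_gt(cosSim, 0.999)
  expect_equal(sum(m@w^2), ref$norm2, tolerance = 1e-3)
  # determinism: duplicated fit gives the identical model
  m2 <- trainLinearSVM(X, y, cost = 1e6)
  expect_identical(m@w, m2@w)
  expect_identical(m@b, m2@b)
  expect_error(trainLinearSVM(X, rep(1, 4), 1), "both classes")
})

test_that("decision scores are the affine form <w,x>+b", {
  m <- new("LinearSVMModel", w = c(2, -1), b = 0.5, cost = 1)
  X <- rbind(c(0, 0.5), c(1, 2.5))  # both on the decision boundary
  expect_equal(decisionScores(m, X), c(0, 0))
  m2 <- new("LinearSVMModel", w = 2 * m@w, b = 2 * m@b, cost = 1)
  X2 <- matrix(rnorm(10), 5, 2)
  expect_equal(decisionScores(m2, X2), 2 * decisionScores(m, X2))
  expect_error(decisionScores(m, matrix(1, 1, 3)), "dimension")
})

test_that("fusion weight grids enumerate the simplex points", {
  w2 <- enumerateFusionWeights(2)
  expect_length(w2, 9L)
  expect_true(all(vapply(w2, sum, 0) == 1))
  expect_true(any(vapply(w2, function(b) all(b == c(0.5, 0.5)), TRUE)))
  expect_length(enumerateFusionWeights(3), 36L)
  # brute-force count for F=3 over the stated grid
  g <- expand.grid(b1 = 1:9, b2 = 1:9, b3 = 1:9)
  expect_equal(sum(rowSums(g) == 10L), 36L)
  expect_equal(enumerateFusionWeights(1), list(1))
})

test_that("score fusion is a convex combination with the stated tie rule", {
  s <- list(c(-1, 2, 0.5), c(-1, 2, 0.5))
  f <- fuse(s, c(0.4, 0.6))
  expect_equal(f$fused, s[[1]])
  f2 <- fuse(list(-1, 10), c(0.9, 0.1))
  expect_equal(f2$fused, 0.1)
  expect_equal(f2$pred, 1)  # NC
  # exact zero fused score predicts NC
  f3 <- fuse(list(1, -1), c(0.5, 0.5))
  expect_equal(f3$pred, 1)
  expect_error(fuse(list(1:3, 1:2), c(0.5, 0.5)), "equal length")
})

test_that("metrics reproduce the worked confusion example", {
  yT <- c(rep(-1, 12), rep(1, 12))
  yP <- c(rep(-1, 10), rep(1, 2), rep(-1, 4), rep(1, 8))
  m <- computeMetrics(yT, yP)
  tab <- metricsTable(m)
  expect_equal(tab$ACC, 75)
  expect_equal(tab$TPR, 83.33, tolerance = 1e-4)
  expect_equal(tab$TNR, 66.67, tolerance = 1e-4)
  expect_equal(tab$PPV, 71.43, tolerance = 1e-4)
  expect_equal(tab$NPV, 80)
  expect_equal(tab$F1, 76.92, tolerance = 1e-4)
  perfect <- computeMetrics(yT, yT)
  expect_equal(unlist(metricsTable(perfect)[1:6]), rep(100, 6),
               ignore_attr = TRUE)
  expect_warning(und <- computeMetrics(c(-1, 1, 1), c(1, 1, 1)), "PPV")
  expect_equal(metricsTable(und)$TPR, 0)
  expect_true(is.nan(metricsTable(und)$PPV))
})

test_that("metric identities and label-swap symmetry hold on random confusions", {
  set.seed(221)
  for (i in 1:20) {
    tp <- sample(1:20, 1); fn <- sample(1:20, 1)
    tn <- sample(1:20, 1); fp <- sample(1:20, 1)
    yT <- c(rep(-1, tp + fn), rep(1, tn + fp))
    yP <- c(rep(-1, tp), rep(1, fn), rep(1, tn), rep(-1, fp))
    m <- metricsTable(computeMetrics(yT, yP))
    expect_equal(m$ACC, 100 * (tp + tn) / (tp + tn + fp + fn))
    expect_equal(m$F1, 2 * m$PPV * m$TPR / (m$PPV + m$TPR))
    # swapping the classes swaps TPR<->TNR and PPV<->NPV
    sw <- metricsTable(computeMetrics(-yT, -yP))
    expect_equal(sw$TPR, m$TNR)
    expect_equal(sw$TNR, m$TPR)
    expect_equal(sw$PPV, m$NPV)
    expect_equal(sw$NPV, m$PPV)
  }
})

# small series-level dataset for CV tests (fast: no EEG synthesis)
cvDataset <- function(delta, seed, H = 40, P = 20) {
  cfg <- synthConfig(RPerGroup = 10, G = 2, noiseSd = 0.1, delta = delta,
                     seed = seed)
  genFCSeries(cfg, H = H, P = P)
}

cvTestConfig <- function(seed, repeats = 2) {
  cvConfig(outerFolds = 10, innerFolds = 3, repeats = repeats, seed = seed,
           kGrid = c(2, 3), pGrid = 0.05, lambdaGrid = c(0.1, 0.5),
           cGrid = 1)
}

test_that("nested CV detects a planted high-order effect", {
  ds <- cvDataset(delta = 2, seed = 23)
  rep <- nestedCV(list(synthetic = ds$series), ds$y, cvTestConfig(23))
  expect_gte(rep$meanFusedAcc, 90)
})

test_that("nested CV is reproducible and audits its fitted-on subjects", {
  ds <- cvDataset(delta = 2, seed = 29)
  cfg <- cvTestConfig(29, repeats = 1)
  r1 <- nestedCV(list(s = ds$series), ds$y, cfg)
  r2 <- nestedCV(list(s = ds$series), ds$y, cfg)
  expect_identical(r1$foldAcc, r2$foldAcc)
  expect_identical(lapply(r1$folds, `[[`, "beta"),
                   lapply(r2$folds, `[[`, "beta"))
  # no fold's models were fitted on its held-out subjects
  for (f in r1$folds) {
    expect_length(intersect(f$fittedOn, f$test), 0L)
    expect_true(all(f$fittedOn %in% f$train))
  }
})

test_that("nested CV is at chance when labels carry no information", {
  ds <- cvDataset(delta = 2, seed = 31)
  set.seed(31)
  yPerm <- sample(ds$y)
  rep <- nestedCV(list(s = ds$series), yPerm, cvTestConfig(31, repeats = 5))
  expect_gte(rep$meanFusedAcc, 35)
  expect_lte(rep$meanFusedAcc, 65)
})

test_that("selection report ranks by count with index tie-break and regions", {
  expect_equal(regionMap(c("E33", "E104")), c(E33 = "LT", E104 = "C"))
  expect_equal(unname(regionMap("E1")), "marginal")
  ds <- cvDataset(delta = 2, seed = 37)
  rep <- nestedCV(list(s = ds$series), ds$y, cvTestConfig(37, repeats = 1))
  # synthetic ranking: construct counts directly
  rep$selection$lo$s <- c(5L, 3L, 5L, 1L, rep(0L, 16))
  sel <- selectionFrequencyReport(rep, topN = 2)
  expect_equal(sel$lowOrder$feature, c(1L, 3L))
  # topN larger than the feature count returns the full ranking
  selAll <- selectionFrequencyReport(rep, topN = 999)
  expect_equal(nrow(selAll$lowOrder), 20L)
  expect_true(all(diff(selAll$lowOrder$count) <= 0))
})
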