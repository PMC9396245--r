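test_that("low-order features average the window matrices", {
  set.seed(131)
  rec <- makeRecording(matrix(rnorm(4 * 100), 4, 100), fs = 100)
  plan <- planWindows(100, 50, 50)
  fc <- buildDynamicFC(rec, plan, "pcc")
  f <- lowOrderFeature(fc)
  expect_length(f, 6L)
  pr <- pairIndex(4)
  expect_equal(f, (fc@tensor[1, , ][pr] + fc@tensor[2, , ][pr]) / 2)
  # single window: the feature is that window's vectorized matrix
  fc1 <- buildDynamicFC(rec, planWindows(100, 100, 1), "pcc")
  expect_equal(lowOrderFeature(fc1), fc1@tensor[1, , ][pr])
})

test_that("high-order features vectorize and round-trip the upper triangle", {
  M2 <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(highOrderFeature(M2), 0.3)
  set.seed(141)
  v <- runif(6, -1, 1)
  M4 <- diag(4)
  M4[t(utils::combn(4, 2))] <- v
  M4 <- (M4 + t(M4)) - diag(diag(M4))
  f <- highOrderFeature(M4)
  expect_length(f, 6L)
  back <- diag(4)
  back[t(utils::combn(4, 2))] <- f
  back <- back + t(back) - diag(diag(back))
  expect_identical(back, M4)
})

test_that("t-test screen agrees with stats::t.test and keeps strong effects", {
  set.seed(151)
  n <- 10
  y <- c(rep(-1, n), rep(1, n))
  X <- cbind(c(rnorm(n, 0, 0.01), rnorm(n, 10, 0.01)),  # huge effect
             rnorm(2 * n),                              # null
             rep(2.5, 2 * n))                           # constant
  mask <- ttestFilter(X, y, 0.05)
  expect_true(1L %in% mask@kept)
  expect_false(3L %in% mask@kept)
  for (j in 1:2) {
    ref <- stats::t.test(X[y < 0, j], X[y > 0, j], var.equal = TRUE)
    expect_equal(mask@detail$p[j], ref$p.value, tolerance = 1e-6)
  }
  # Welch variant against its oracle
  maskW <- ttestFilter(X, y, 0.05, welch = TRUE)
  refW <- stats::t.test(X[y < 0, 1], X[y > 0, 1])
  expect_equal(maskW@detail$p[1], refW$p.value, tolerance = 1e-6)
  expect_error(ttestFilter(X, rep(-1, 2 * n), 0.05), "per class")
})

test_that("t-test masks are monotone in the significance level", {
  set.seed(161)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 15), 20, 15)
    y <- rep(c(-1, 1), each = 10)
    m1 <- ttestFilter(X, y, 0.01)@kept
    m5 <- ttestFilter(X, y, 0.05)@kept
    expect_true(all(m1 %in% m5))
  }
})

test_that("LASSO matches the exhaustive grid oracle on 2-feature toys", {
  set.seed(171)
  n <- 6
  X <- matrix(rnorm(n * 2), n, 2)
  y <- c(1, 1, 1, -1, -1, -1)
  lam <- 0.5
  sel <- lassoSelect(X, y, lam)
  # evaluate both on the internally standardized problem
  Xs <- scale(X)
  yc <- y - mean(y)
  ours <- lassoObjective(sel@detail$alpha, Xs, yc, lam)
  oracle <- lassoGridOracle(Xs, yc, lam)
  expect_lt(ours - oracle["obj"], 1e-6)
})

test_that("LASSO limits: kill bound empties the mask, lambda 0 is OLS", {
  set.seed(181)
  n <- 8
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c(-1, 1), 4)
  Xs <- scale(X)
  yc <- y - mean(y)
  lamKill <- max(abs(crossprod(Xs, yc))) * (1 + 1e-6)
  expect_length(lassoSelect(X, y, lamKill)@kept, 0L)
  # lambda = 0 on a full-rank 3x2 problem equals least squares
  X2 <- matrix(c(1, 2, 4, 8, -3, 5), 3, 2)
  y2 <- c(1, -1, 1)
  sel0 <- lassoSelect(X2, y2, 0)
  ref <- stats::lm.fit(scale(X2), y2 - mean(y2))$coefficients
  expect_equal(sel0@detail$alpha, unname(ref), tolerance = 1e-8)
  expect_error(lassoSelect(X, y, -0.1), "lambda")
  # single-column closed form agrees with the objective over a fine grid
  x1 <- matrix(rnorm(n), n, 1)
  s1 <- lassoSelect(x1, y, 0.8)
  g <- seq(-3, 3, by = 1e-4)
  objs <- vapply(g, function(a)
    lassoObjective(a, scale(x1), y - mean(y), 0.8), 0)
  expect_lt(lassoObjective(s1@detail$alpha, scale(x1), y - mean(y), 0.8) -
              min(objs), 1e-6)
})

test_that("LASSO support shrinks (weakly) along the lambda path", {
  set.seed(191)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(c(-1, 1), each = 10)
    sizes <- vapply(c(0.1, 0.5, 1, 2, 5, 10),
                    function(l) length(lassoSelect(X, y, l)@kept), 0L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("chi-square reproduces the cohort gender comparison", {
  res <- chi2Test2x2(rbind(c(12, 12), c(20, 9)))
  expect_equal(round(res$p, 4), 0.16)
  # cross-check against the stock implementation without correction
  ref <- suppressWarnings(stats::chisq.test(rbind(c(12, 12), c(20, 9)),
                                            correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("chi-square analytic values and invariances", {
  res <- chi2Test2x2(rbind(c(10, 10), c(20, 20)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  resD <- chi2Test2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(resD$statistic, 20)
  expect_lt(resD$p, 1e-4)
  set.seed(201)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    expect_equal(chi2Test2x2(tab)$statistic, chi2Test2x2(t(tab))$statistic,
                 tolerance = 1e-12)
  }
  expect_error(chi2Test2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("summary t-test reproduces the questionnaire comparison", {
  res <- tFromSummary(24, 18.3, 7.3, 29, 2.6, 2.6)
  expect_equal(round(res$p, 4), 0)
  expect_gt(res$t, 10)
  # equal summaries give t = 0, p = 1
  res0 <- tFromSummary(10, 5, 1, 10, 5, 1)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("summary t-test agrees with raw-data t on constructed samples", {
  set.seed(211)
  a <- sampleWithSummary(10, 1, 1)
  b <- sampleWithSummary(10, 2, 1)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  res <- tFromSummary(10, 1, 1, 10, 2, 1)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  refW <- stats::t.test(a, b)
  resW <- tFromSummary(10, 1, 1, 10, 2, 1, welch = TRUE)
  expect_equal(resW$p, refW$p.value, tolerance = 1e-10)
})
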