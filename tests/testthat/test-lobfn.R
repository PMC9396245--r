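test_that("window plan arithmetic follows H = floor((M-W)/s) + 1", {
  plan <- planWindows(75000, 10000, 1000)
  expect_equal(nWindows(plan), 66L)
  expect_equal(plan@starts[1], 0L)
  expect_equal(plan@starts[66], 65000L)
  # single exact-fit window
  plan1 <- planWindows(100, 100, 7)
  expect_equal(nWindows(plan1), 1L)
  expect_equal(plan1@starts, 0L)
  expect_error(planWindows(50, 100, 10), "exceeds")
  expect_error(planWindows(100, 10, 0), ">= 1")
})

test_that("windows stay inside the recording and H is monotone in s", {
  set.seed(21)
  for (i in 1:25) {
    M <- sample(50:500, 1)
    W <- sample(seq_len(M), 1)
    s <- sample(1:50, 1)
    plan <- planWindows(M, W, s)
    expect_true(all(plan@starts >= 0L))
    expect_true(all(plan@starts + plan@W <= M))
    expect_equal(plan@H, length(plan@starts))
    s2 <- s + sample(1:20, 1)
    expect_lte(planWindows(M, W, s2)@H, plan@H)
  }
})

test_that("phase lag index analytic cases", {
  phi <- runif(200, -pi, pi)
  # identical phases: sign(0) = 0
  expect_equal(pliMatrix(rbind(phi, phi))[1, 2], 0)
  # constant quarter-cycle lag: all signs equal
  lag <- ((phi - pi / 2 + pi) %% (2 * pi)) - pi
  expect_equal(pliMatrix(rbind(phi, lag))[1, 2], 1)
  # alternating +0.3 / -0.3 differences cancel over even N
  base <- rep(0.5, 100)
  alt <- base - rep(c(0.3, -0.3), 50)
  expect_equal(pliMatrix(rbind(base, alt))[1, 2], 0)
})

test_that("independent uniform phases give near-zero PLI (Monte Carlo)", {
  # |mean of N=10000 random signs| is below 0.05 with overwhelming
  # probability; check the exceedance rate over 1000 replicates
  set.seed(5)
  N <- 10000
  reps <- 1000
  vals <- replicate(reps, {
    abs(sum(sign(sin(runif(N, -pi, pi) - runif(N, -pi, pi))))) / N
  })
  expect_gte(mean(vals < 0.05), 0.99)
})

test_that("PLI is bounded, symmetric, zero-diagonal and offset-invariant", {
  set.seed(31)
  for (i in 1:10) {
    ph <- matrix(runif(5 * 60, -pi, pi), 5, 60)
    P <- pliMatrix(ph)
    expect_true(all(P >= 0 & P <= 1))
    expect_identical(P, t(P))
    expect_equal(diag(P), rep(0, 5))
    # common phase offset leaves every pairwise difference unchanged
    off <- runif(1, -pi, pi)
    ph2 <- (ph + off + pi) %% (2 * pi) - pi
    expect_equal(pliMatrix(ph2), P, tolerance = 1e-12)
  }
})

test_that("Pearson window matrix handles exact and degenerate cases", {
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(pccMatrix(rbind(x, 2 * x + 3))[1, 2], 1)
  expect_equal(pccMatrix(rbind(x, -x))[1, 2], -1)
  # even function kills the covariance
  expect_equal(pccMatrix(rbind(x, x^2))[1, 2], 0)
  expect_warning(P <- pccMatrix(rbind(x, rep(1, 5), x^2)), "zero-variance")
  expect_equal(P[2, ], c(0, 1, 0))
  # affine invariance with positive slope
  set.seed(41)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(pccMatrix(rbind(3 * a + 1, b)), pccMatrix(rbind(a, b)),
               tolerance = 1e-12)
})

test_that("dynamic FC equals per-window matrices for both estimators", {
  set.seed(51)
  rec <- makeRecording(matrix(rnorm(4 * 200), 4, 200), fs = 100)
  plan <- planWindows(200, 80, 40)
  expect_equal(nWindows(plan), 4L)
  fcP <- buildDynamicFC(rec, plan, "pcc")
  ph <- instantaneousPhase(rec)
  fcL <- buildDynamicFC(ph, plan, "pli")
  for (h in 1:4) {
    idx <- (plan@starts[h] + 1):(plan@starts[h] + 80)
    expect_equal(fcP@tensor[h, , ], pccMatrix(rec@data[, idx]),
                 tolerance = 1e-12)
    expect_equal(fcL@tensor[h, , ], pliMatrix(ph@data[, idx]),
                 tolerance = 1e-12)
  }
  expect_error(buildDynamicFC(rec, planWindows(100, 50, 10), "pcc"),
               "plan")
  expect_error(buildDynamicFC(rec, plan, "pli"), "PhaseSeries")
})

test_that("stationary coupled pair keeps PLI near 1 in every window", {
  rec <- sineRecording(c(10, 10), fs = 250, M = 2000,
                       phases = c(0, -pi / 2))
  fc <- buildDynamicFC(instantaneousPhase(rec), planWindows(2000, 500, 250),
                       "pli")
  expect_true(all(fc@tensor[, 1, 2] > 0.98))
})

test_that("windowed PLI follows a planted on/off coupling schedule", {
  cfg <- synthConfig(RPerGroup = 1, E = 4, G = 2, duration = 120,
                     noiseSd = 0.05, delta = 0, seed = 7)
  ds <- genEEG(cfg)
  rec <- bandpass(ds$recordings[[1]], standardBands()$alpha)
  plan <- planWindows(nSamples(rec), 2500, 1250)
  fc <- buildDynamicFC(instantaneousPhase(rec), plan, "pli")
  planted <- plantedCouplingSeries(ds$truth$states[[1]], cfg@segLen, plan)
  # channels 1,2 belong to module 1
  expect_gt(cor(fc@tensor[, 1, 2], planted[1, ]), 0.9)
})

test_that("series vectorization uses canonical pair order and round-trips", {
  expect_equal(pairIndex(3), cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  expect_equal(nrow(pairIndex(128)), 8128L)
  set.seed(61)
  rec <- makeRecording(matrix(rnorm(3 * 120), 3, 120), fs = 100)
  fc <- buildDynamicFC(rec, planWindows(120, 40, 40), "pcc")
  s <- toSeries(fc)
  expect_equal(dim(seriesMatrix(s)), c(3L, 3L))
  # rebuild the symmetric matrices from the series rows
  pr <- pairIndexOf(s)
  for (h in 1:3) {
    M <- matrix(0, 3, 3)
    M[pr] <- seriesMatrix(s)[, h]
    M <- M + t(M)
    diag(M) <- 1
    expect_identical(M, fc@tensor[h, , ])
  }
})
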