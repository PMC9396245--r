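test_that("matrix recordings load with auto-detected delimiters", {
  dir <- withr::local_tempdir()
  X <- matrix(seq_len(300) / 7, 3, 100)
  for (sep in c(",", "\t", " ")) {
    path <- file.path(dir, paste0("rec", which(sep == c(",", "\t", " ")),
                                  ".txt"))
    writeLines(apply(X, 1L, paste, collapse = sep), path)
    rec <- loadRecording(path, format = "matrix", fs = 250)
    expect_equal(nChannels(rec), 3L)
    expect_equal(nSamples(rec), 100L)
    expect_equal(rec@data, X, ignore_attr = TRUE)
    expect_equal(samplingRate(rec), 250)
  }
})

test_that("matrix loader reads fs from the JSON sidecar and round-trips", {
  dir <- withr::local_tempdir()
  rec <- makeRecording(matrix(rnorm(40), 4, 10), fs = 125, id = "sub7")
  path <- file.path(dir, "sub7.csv")
  writeRecording(rec, path)
  back <- loadRecording(path, format = "matrix")
  expect_equal(samplingRate(back), 125)
  expect_equal(back@data, rec@data, tolerance = 1e-12)
})

test_that("malformed matrix inputs error", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("1,2,3", "4,x,6"), bad)
  expect_error(loadRecording(bad, fs = 100), "non-numeric")
  ragged <- file.path(dir, "ragged.csv")
  writeLines(c("1,2,3", "4,5"), ragged)
  expect_error(loadRecording(ragged, fs = 100), "ragged")
  one <- file.path(dir, "one.csv")
  writeLines("1,2,3", one)
  expect_error(loadRecording(one, fs = 100), "2 channels")
  expect_error(loadRecording(file.path(dir, "absent.csv"), fs = 100),
               "not found")
})

test_that("EDF files round-trip through the reader", {
  dir <- withr::local_tempdir()
  fs <- 100
  t <- (0:499) / fs
  X <- rbind(50 * sin(2 * pi * 5 * t), 80 * cos(2 * pi * 11 * t),
             10 * sin(2 * pi * 2 * t))
  path <- file.path(dir, "rec.edf")
  writeTestEDF(path, X, fs)
  rec <- loadRecording(path, format = "edf")
  expect_equal(nChannels(rec), 3L)
  expect_equal(nSamples(rec), 500L)
  expect_equal(samplingRate(rec), fs)
  expect_equal(rec@data, X, tolerance = 1e-2, ignore_attr = TRUE)
  expect_equal(rec@channelLabels, c("sig1", "sig2", "sig3"))
})

test_that("ragged EDF signals are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ragged.edf")
  writeTestEDF(path, matrix(rnorm(200), 2, 100), fs = 50,
               sprOverride = c(50L, 40L))
  expect_error(loadRecording(path, format = "edf"), "ragged")
})

test_that("bandpass passes, annihilates and separates pure tones", {
  fs <- 250
  bands <- standardBands()
  rec10 <- sineRecording(c(10, 10), fs = fs, M = 500)
  # passband identity
  out <- bandpass(rec10, bands$alpha)
  relerr <- sqrt(signalEnergy(out@data - rec10@data) /
                   signalEnergy(rec10@data))
  expect_lt(relerr, 1e-8)
  expect_equal(bandName(out), "alpha")
  # stopband annihilation
  out <- bandpass(rec10, bands$theta)
  expect_lt(signalEnergy(out@data), 1e-10 * signalEnergy(rec10@data))
  # linearity: 5 Hz + 20 Hz, beta recovers the 20 Hz part alone
  t <- (0:499) / fs
  mix <- makeRecording(rbind(sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t),
                             cos(2 * pi * 5 * t) + cos(2 * pi * 20 * t)),
                       fs = fs)
  pure20 <- rbind(sin(2 * pi * 20 * t), cos(2 * pi * 20 * t))
  out <- bandpass(mix, bands$beta)
  expect_lt(sqrt(signalEnergy(out@data - pure20) / signalEnergy(pure20)),
            1e-8)
})

test_that("bandpass is an idempotent orthogonal projection", {
  set.seed(11)
  rec <- makeRecording(matrix(rnorm(2 * 300), 2, 300), fs = 250)
  band <- standardBands()$alpha
  once <- bandpass(rec, band)
  twice <- bandpass(once, band)
  expect_equal(twice@data, once@data, tolerance = 1e-10)
  expect_equal(dim(once@data), dim(rec@data))
  # Parseval: passband + residual energies sum to the input energy
  resid <- rec@data - once@data
  expect_equal(signalEnergy(once@data) + signalEnergy(resid),
               signalEnergy(rec@data), tolerance = 1e-8)
  expect_error(bandpass(rec, bandSpec("wide", 10, 130)), "Nyquist")
})

test_that("instantaneous phase matches the analytic signal of cosines", {
  fs <- 250
  rec <- sineRecording(c(10, 10, 10), fs = fs, M = 1000,
                       phases = c(0, -pi / 2, 0))
  rec@data[3, ] <- 3 * rec@data[3, ]
  ph <- instantaneousPhase(rec)
  expect_true(all(ph@data <= pi + 1e-12 & ph@data > -pi - 1e-12))
  interior <- 100:900
  # phase advances by 2*pi*f/fs per sample
  d <- diff(ph@data[1, interior])
  d <- (d + pi) %% (2 * pi) - pi
  expect_lt(max(abs(d - 2 * pi * 10 / fs)), 1e-3)
  # a quarter-cycle lag shows up as a pi/2 phase difference
  dphi <- (ph@data[1, interior] - ph@data[2, interior] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - pi / 2)), 1e-3)
  # amplitude invariance
  expect_lt(max(abs(ph@data[1, ] - ph@data[3, ])), 1e-10)
})

test_that("constant channels are rejected by name", {
  rec <- makeRecording(rbind(rep(1, 100), rnorm(100)), fs = 100)
  expect_error(instantaneousPhase(rec), "ch1")
})

test_that("EEGRecording validity enforces its invariants", {
  expect_error(makeRecording(matrix(1:4, 1, 4)), "2 channels")
  expect_error(makeRecording(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
  expect_error(makeRecording(matrix(rnorm(8), 2, 4), fs = -1), "positive")
  expect_error(new("EEGRecording", subjectId = "s", fs = 10,
                   data = matrix(rnorm(8), 2, 4),
                   channelLabels = c("a", "a"), band = "time"), "unique")
})
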