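makeSeries <- function(voxelSeries, tr = 2) {
  # tiny 2x2 grid whose first voxel carries `voxelSeries`, rest constant
  nt <- length(voxelSeries)
  d <- array(100, c(2, 2, nt))
  d[1, 1, ] <- voxelSeries
  new("BoldSeries", data = d, tr = tr, mask = array(TRUE, c(2, 2)))
}

test_that("motion QC applies strict 3 mm / 3 degree thresholds", {
  zeros <- matrix(0, 200, 6)
  expect_true(qcMotion(zeros)$pass)

  m <- zeros; m[37, 1] <- 3.1
  qc <- qcMotion(m)
  expect_false(qc$pass)
  expect_identical(qc$offending, 37L)

  m2 <- zeros; m2[10, 4] <- -3.2           # rotation on any axis, signed
  expect_false(qcMotion(m2)$pass)

  m3 <- zeros; m3[5, 2] <- 3.0; m3[8, 6] <- 3.0   # exactly at threshold
  expect_true(qcMotion(m3)$pass)

  expect_error(qcMotion(zeros, nVolumes = 100), "100")
  expect_error(qcMotion(zeros[, 1:4]), "6 columns")
})

test_that("initial-volume trimming drops exactly the first n volumes", {
  lab <- matrix(1L, 8, 8)
  gb <- generateBoldSeries(lab, list(), tr = 2, nVolumes = 200, seed = 1,
                           noiseSd = 1)
  trimmed <- trimInitial(gb$series, 15)
  expect_identical(tail(dim(seriesData(trimmed)), 1), 185L)
  expect_equal(repetitionTime(trimmed), 2)
  expect_equal(seriesData(trimmed)[3, 3, ],
               seriesData(gb$series)[3, 3, 16:200])
  expect_identical(trimInitial(gb$series, 0), gb$series)
  short <- generateBoldSeries(lab, list(), tr = 2, nVolumes = 32,
                              seed = 1)$series
  expect_error(trimInitial(short, 32), "cannot drop")
})

test_that("ALFF of pure sinusoids matches a direct DFT oracle", {
  tt <- (0:239) * 2
  inBand <- 100 + 3 * sin(2 * pi * 0.05 * tt)
  outBand <- 100 + 3 * sin(2 * pi * 0.15 * tt)

  alffIn <- computeALFF(makeSeries(inBand))
  alffOut <- computeALFF(makeSeries(outBand))
  vIn <- mapValues(alffIn)[1, 1]
  vOut <- mapValues(alffOut)[1, 1]

  # oracle: mean one-sided DFT amplitude over 0.01-0.08 Hz of the
  # linearly detrended series (lm residuals; the loop DFT is independent)
  oracleFor <- function(x) {
    sp <- dftAmplitudeOracle(stats::residuals(stats::lm(x ~ seq_along(x))),
                             tr = 2)
    mean(sp$amp[sp$freq >= 0.01 & sp$freq <= 0.08])
  }
  expect_equal(vIn, oracleFor(inBand), tolerance = 1e-8)
  expect_equal(vOut, oracleFor(outBand), tolerance = 1e-8)
  expect_gte(vIn / max(vOut, 1e-300), 10)

  # constant series: zero after detrending, DC excluded
  expect_equal(mapValues(computeALFF(makeSeries(rep(7, 240))))[1, 1], 0)

  # linearity: scaling the series scales ALFF
  expect_equal(mapValues(computeALFF(makeSeries(3 * inBand)))[1, 1],
               3 * vIn, tolerance = 1e-8)
})

test_that("ALFF band handling: Nyquist guard and sub-band additivity", {
  s <- makeSeries(100 + rnorm(240, 0, 5))
  expect_error(computeALFF(s, band = c(0.01, 0.3)), "Nyquist")
  expect_error(computeALFF(s, band = c(0.05, 0.02)), "low < high")

  # two disjoint sub-bands with equal bin counts average to the union
  # (bins at k/480 Hz: 0.01-0.0396 covers k=5..19, 0.04-0.0709 k=20..34)
  a1 <- mapValues(computeALFF(s, band = c(0.01, 0.0396)))[1, 1]
  a2 <- mapValues(computeALFF(s, band = c(0.04, 0.0709)))[1, 1]
  aU <- mapValues(computeALFF(s, band = c(0.01, 0.0709)))[1, 1]
  expect_equal((a1 + a2) / 2, aU, tolerance = 1e-10)
})

test_that("in-ROI ALFF rises monotonically with injected amplitude", {
  lab <- trueLabels(generateTissuePhantom(c(16, 16), c(20, 120, 220), 0))
  meanRoiAlff <- function(A) {
    gb <- generateBoldSeries(
      lab, list(oscillationSpec(2, 0.05, A, noiseSd = 1)),
      tr = 2, nVolumes = 240, seed = 17, noiseSd = 1)
    am <- computeALFF(gb$series)
    mean(mapValues(am)[lab == 2])
  }
  vals <- vapply(c(1, 2, 4), meanRoiAlff, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("mALFF divides by the in-mask mean", {
  mk <- function(v) new("ALFFMap", values = array(v, c(3, 1)),
                        band = c(0.01, 0.08),
                        mask = array(TRUE, c(3, 1)))
  m <- computeMALFF(mk(c(1, 2, 3)))
  expect_equal(as.vector(mapValues(m)), c(0.5, 1.0, 1.5))
  expect_equal(mean(mapValues(m)[brainMask(m)]), 1)
  expect_equal(as.vector(mapValues(computeMALFF(mk(c(4, 4, 4))))),
               c(1, 1, 1))
  expect_error(computeMALFF(mk(c(0, 0, 0))), "positive")
})

test_that("zALFF standardisation is exact and scale-invariant", {
  mk <- function(v) new("ALFFMap", values = array(v, c(3, 1)),
                        band = c(0.01, 0.08),
                        mask = array(TRUE, c(3, 1)))
  z <- computeZALFF(mk(c(1, 2, 3)))
  expect_equal(as.vector(mapValues(z)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z@sourceMean, 2)
  expect_equal(z@sourceSd, sqrt(2 / 3))
  expect_error(computeZALFF(mk(c(5, 5, 5))), "constant")

  # sample-SD convention remains a valid unit-SD construction
  zs <- computeZALFF(mk(c(1, 2, 3)), sdType = "sample")
  expect_equal(zs@sourceSd, 1)

  # zALFF is invariant to global rescaling of the raw series
  tt <- (0:239) * 2
  set.seed(1)
  base <- 100 + 3 * sin(2 * pi * 0.05 * tt) + rnorm(240, 0, 1)
  s1 <- makeSeries(base)
  s2 <- makeSeries(5 * base)
  expect_equal(mapValues(computeZALFF(computeALFF(s2))),
               mapValues(computeZALFF(computeALFF(s1))), tolerance = 1e-9)
})

test_that("nuisance residualisation removes a known regressor", {
  nt <- 64
  reg <- sin(2 * pi * 0.11 * (0:(nt - 1)) * 2)
  d <- array(100, c(2, 2, nt))
  d[1, 1, ] <- 100 + 5 * reg + rnorm(nt, 0, 0.1)
  ser <- new("BoldSeries", data = d, tr = 2, mask = array(TRUE, c(2, 2)))
  res <- residualizeSeries(ser, matrix(reg))
  v <- seriesData(res)[1, 1, ]
  expect_lt(abs(sum((v - mean(v)) * reg)), 1e-6)   # orthogonal to regressor
  expect_equal(mean(v), mean(d[1, 1, ]), tolerance = 1e-9)
})
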