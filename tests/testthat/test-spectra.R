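test_that("Welch segment arithmetic matches the study geometry", {
  expect_equal(welchSegmentLength(180, 8, 0.5), 40)
  expect_equal(welchSegmentLength(36, 8, 0.5), 8)
  expect_error(welchSegmentLength(180, 8, 1.2))
})

test_that("DFT power and phase agree with brute-force summation", {
  # oracle: O(N^2) complex summation on tiny signals
  set.seed(3)
  for (n in c(4L, 6L, 8L)) {
    x <- rnorm(n)
    ours <- ppafuse:::.dftCoef(x)
    oracle <- bruteDft(x)
    expect_lt(max(abs(Mod(ours)^2 - Mod(oracle)^2)), 1e-10)
    keep <- Mod(oracle) > 1e-8
    expect_lt(max(abs(ppafuse:::wrapAngle(Arg(ours[keep]) -
                                          Arg(oracle[keep])))), 1e-10)
  }
})

test_that("pure tones concentrate Welch power at their own bin", {
  t <- timeAxis(36, 200)     # 8 s segments, exact integer bins
  rec <- toneRecording(cos(2 * pi * 10 * t), fs = 200)
  p <- spectrumPower(welchSpectrum(rec))[1, ]
  expect_gt(p[10], 1)
  expect_lt(p[20] / p[10], 1e-6)
  expect_lt(p[47] / p[10], 1e-6)
})

test_that("white-noise band-integrated Welch power recovers the variance", {
  # Parseval: one-sided density integrated over 1..100 Hz at fs = 200
  # should give back sigma^2 (minus the sub-1 Hz sliver)
  sigma <- 1.7
  est <- vapply(1:10, function(s) {
    set.seed(s)
    rec <- toneRecording(rnorm(36 * 200, sd = sigma), fs = 200)
    sum(spectrumPower(welchSpectrum(rec))[1, ])   # df = 1 Hz
  }, numeric(1))
  expect_equal(mean(est), sigma^2, tolerance = 0.1)
})

test_that("Welch estimates are stable under circular time shift", {
  set.seed(21)
  x <- rnorm(36 * 200)
  p0 <- spectrumPower(welchSpectrum(toneRecording(x, 200)))[1, ]
  ps <- spectrumPower(welchSpectrum(toneRecording(
    c(x[-(1:100)], x[1:100]), 200)))[1, ]
  expect_equal(mean(ps), mean(p0), tolerance = 0.02)
})

test_that("full-record phases follow the cosine convention and shift theorem", {
  fs <- 250; t <- timeAxis(4, fs)
  ph <- function(x) spectrumPhase(fftPhases(toneRecording(x, fs)))[1, ]
  expect_equal(unname(ph(cos(2 * pi * 10 * t))[10]), 0,
               tolerance = 1e-9)
  expect_equal(unname(ph(sin(2 * pi * 10 * t))[10]), -pi / 2,
               tolerance = 1e-9)
  # delaying by dt rotates theta(f) by -2 pi f dt (mod 2 pi)
  dt <- 3 / fs
  shifted <- ph(cos(2 * pi * 10 * (t - dt)))
  base <- ph(cos(2 * pi * 10 * t))
  d <- unname(shifted[10] - base[10]) %% (2 * pi)
  expect_equal(d, (-2 * pi * 10 * dt) %% (2 * pi), tolerance = 1e-9)
  # non-integer-second durations are rejected, not interpolated
  expect_error(fftPhases(toneRecording(rnorm(1001), 250)),
               "integer number of seconds")
})

test_that("band dB reduction follows 10 log10 of the band mean", {
  flat <- new("SpectrumSet", power = matrix(1, 1, 100),
              phase = matrix(0, 0, 0))
  expect_equal(unname(bandPsdFeatures(flat)[1, ]), rep(0, 6))
  ten <- new("SpectrumSet", power = matrix(10, 1, 100),
             phase = matrix(0, 0, 0))
  expect_equal(unname(bandPsdFeatures(ten)[1, "theta"]), 10)
  # alpha band averages exactly its 6 inclusive bins
  s <- bandScheme()
  expect_identical(s$hi[s$band == "alpha"] - s$lo[s$band == "alpha"] + 1L, 6L)
  pw <- matrix(0.001, 1, 100); pw[1, 8:13] <- 100
  spec <- new("SpectrumSet", power = pw, phase = matrix(0, 0, 0))
  expect_equal(unname(bandPsdFeatures(spec)[1, "alpha"]), 20)
  expect_error(bandPsdFeatures(flat, data.frame(band = "x", lo = 90,
                                                hi = 120)),
               "inside the 1..100")
})

test_that("preferred phase angle is the circular mean of unit phasors", {
  r <- preferredPhaseAngle(rep(1.2, 5))
  expect_equal(r$ppa, 1.2)
  expect_equal(r$consistency, 1)
  expect_false(r$degenerate)
  r2 <- preferredPhaseAngle(c(pi / 3, -pi / 3))
  expect_equal(r2$ppa, 0)
  expect_equal(r2$consistency, cos(pi / 3))
  # uniformly spaced phasors: vanishing resultant, flagged
  r3 <- preferredPhaseAngle(seq(-pi, pi, length.out = 9)[-9])
  expect_equal(r3$ppa, 0)
  expect_true(r3$degenerate)
  expect_lt(r3$consistency, 1e-12)
})

test_that("PPA is amplitude-invariant; PSD shifts by 20 log10(scale)", {
  g <- smallCohort("both", nPerClass = 1L, seed = 4)
  rec <- g$recordings[[1]]
  rec2 <- newRecording(3.7 * recordingData(rec), fs = samplingRate(rec),
                       subjectId = "scaled")
  ppa1 <- bandPpaFeatures(fftPhases(rec))$ppa
  ppa2 <- bandPpaFeatures(fftPhases(rec2))$ppa
  expect_equal(ppa1, ppa2, tolerance = 1e-9, ignore_attr = TRUE)
  psd1 <- bandPsdFeatures(welchSpectrum(rec))
  psd2 <- bandPsdFeatures(welchSpectrum(rec2))
  expect_equal(psd2 - psd1,
               matrix(20 * log10(3.7), nrow(psd1), ncol(psd1)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("adding a constant phase rotates PPA and keeps consistency", {
  set.seed(9)
  th <- runif(6, -pi, pi)
  base <- preferredPhaseAngle(th)
  for (dc in c(0.3, 2.5, -1.1)) {
    rot <- preferredPhaseAngle(ppafuse:::wrapAngle(th + dc))
    expect_equal(ppafuse:::wrapAngle(rot$ppa - base$ppa - dc), 0,
                 tolerance = 1e-12)
    expect_equal(rot$consistency, base$consistency, tolerance = 1e-12)
    expect_true(rot$consistency >= 0 && rot$consistency <= 1)
  }
})

test_that("feature extraction lays out channel-major, band-minor columns", {
  g <- smallCohort("both", nPerClass = 2L, seed = 6)
  fm <- extractFeatureMatrix(g, "PSD")
  expect_identical(dim(featureValues(fm)), c(4L, 20L * 6L))
  info <- featureInfo(fm)
  expect_identical(info$band[1:6], bandScheme()$band)
  expect_identical(info$channel[7], channelNames(deskMontage())[2])
  expect_identical(kindTag(fm), "PSD")
  expect_identical(unname(subjectLabels(fm)),
                   vapply(g$recordings, recordingLabel, character(1)))
  # single-channel single-subject: 1 x 6
  one <- list(newRecording(matrix(rnorm(9 * 250), 1, 9 * 250), fs = 250))
  expect_identical(dim(featureValues(extractFeatureMatrix(one, "PPA"))),
                   c(1L, 6L))
  # heterogeneous cohorts are rejected
  bad <- c(g$recordings[1],
           list(newRecording(matrix(rnorm(9 * 250), 1), fs = 250)))
  expect_error(extractFeatureMatrix(bad, "PSD"), "heterogeneous")
})
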