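test_that("the von Mises sampler concentrates around mu as kappa grows", {
  set.seed(6)
  rbar <- vapply(c(0.5, 2, 8, 32), function(k)
    Mod(mean(exp(1i * rvonmises(2000, 1, k)))), numeric(1))
  expect_true(all(diff(rbar) > 0))          # resultant length rises with kappa
  expect_equal(circMean(rvonmises(5000, -2.5, 8)), -2.5, tolerance = 0.05)
  u <- rvonmises(5000, 0, 0)                # kappa = 0: uniform
  expect_lt(Mod(mean(exp(1i * u))), 0.05)
  expect_error(rvonmises(10, 0, -1))
})

test_that("recordings are seed-deterministic with the specified structure", {
  spec <- effectSpec(amplitude = c(theta = 1), mu = c(theta = 0.5),
                     kappa = c(theta = 5), affectedChannels = 1:2)
  g1 <- generateRecording(spec, duration = 5, fs = 250, nChannels = 4,
                          seed = 99)
  g2 <- generateRecording(spec, duration = 5, fs = 250, nChannels = 4,
                          seed = 99)
  expect_identical(recordingData(g1$recording), recordingData(g2$recording))
  expect_identical(g1$phases, g2$phases)
  expect_true(all(is.na(g1$phases[3, ])))   # unaffected channel: pure noise
  expect_identical(which(!is.na(g1$phases[1, ])), 4:8)  # theta bins only
  expect_error(generateRecording(spec, duration = 5.5, fs = 250),
               "integer number of seconds")
  expect_error(generateRecording(spec, nChannels = 1L), "montage")
})

test_that("zero-amplitude specs generate flat white noise", {
  spec <- effectSpec(noiseSd = 1)
  g <- generateRecording(spec, duration = 36, fs = 200, nChannels = 1,
                         seed = 12)
  p <- spectrumPower(welchSpectrum(g$recording))[1, ]
  # flat density: band means all within sampling error of 1/100 sigma^2/Hz
  psd <- bandPsdFeatures(welchSpectrum(g$recording))
  expect_lt(max(psd) - min(psd), 2.5)       # dB spread of band means
  expect_equal(sum(p), 1, tolerance = 0.15) # total power ~ sigma^2
})

test_that("a near-degenerate phase distribution pins the measured PPA", {
  spec <- effectSpec(amplitude = c(alpha = 1), mu = c(alpha = 1.0),
                     kappa = c(alpha = 1e6), affectedChannels = 1L)
  g <- generateRecording(spec, duration = 30, fs = 250, nChannels = 2,
                         seed = 5)
  ppa <- bandPpaFeatures(fftPhases(g$recording))$ppa
  expect_equal(ppa[1, "alpha"], 1.0, tolerance = 0.01)
  cons <- bandPpaFeatures(fftPhases(g$recording))$consistency
  expect_gt(cons[1, "alpha"], 0.99)
})

test_that("measured PPA spread shrinks monotonically in kappa", {
  spread <- vapply(c(0.5, 2, 8, 32), function(k) {
    spec <- effectSpec(amplitude = c(theta = 1), mu = c(theta = 0.8),
                       kappa = c(theta = k), affectedChannels = 1L)
    ppas <- vapply(1:30, function(s) {
      g <- generateRecording(spec, duration = 10, fs = 250, nChannels = 1,
                             seed = 1000 + s)
      bandPpaFeatures(fftPhases(g$recording))$ppa[1, "theta"]
    }, numeric(1))
    1 - Mod(mean(exp(1i * ppas)))           # circular variance
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("true preferred angles are exposed only where defined", {
  specs <- cohortPreset("phase-only")
  expect_equal(truePpa(specs$specASD, "theta"), pi / 2)
  expect_error(truePpa(specs$specASD, "alpha"), "kappa = 0")
  expect_error(truePpa(specs$specASD, "sigma"), "unknown band")
})

test_that("cohorts are balanced, labeled and carry their truth", {
  g <- smallCohort("null", nPerClass = 3L, seed = 7)
  labs <- vapply(g$recordings, recordingLabel, character(1))
  expect_identical(labs, rep(c("TD", "ASD"), each = 3))
  expect_identical(vapply(g$recordings, subjectId, character(1))[c(1, 4)],
                   c("TD01", "ASD01"))
  expect_identical(g$truth$specTD, g$truth$specASD)   # null: no class signal
  g2 <- smallCohort("null", nPerClass = 3L, seed = 7)
  expect_identical(recordingData(g2$recordings[[2]]),
                   recordingData(g$recordings[[2]]))
  specs <- cohortPreset("power-only")
  expect_error(generateCohort(2, specs$specTD,
                              effectSpec(scheme = bandScheme()[1:3, ]),
                              seed = 1),
               "share a band scheme")
})

test_that("class band-power contrast tracks the amplitude ratio in dB", {
  # high SNR: amplitude 2 vs 1 on theta should separate by ~6.02 dB
  mk <- function(a) effectSpec(amplitude = c(theta = a),
                               kappa = c(theta = 0), noiseSd = 0.1,
                               affectedChannels = 1L)
  d <- vapply(1:10, function(s) {
    g1 <- generateRecording(mk(1), duration = 30, fs = 250, nChannels = 1,
                            seed = s)
    g2 <- generateRecording(mk(2), duration = 30, fs = 250, nChannels = 1,
                            seed = 100 + s)
    bandPsdFeatures(welchSpectrum(g2$recording))[1, "theta"] -
      bandPsdFeatures(welchSpectrum(g1$recording))[1, "theta"]
  }, numeric(1))
  expect_equal(mean(d), 20 * log10(2), tolerance = 1)
})
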