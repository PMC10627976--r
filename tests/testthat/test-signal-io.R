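test_that("save/load round trip preserves data, fs, names and label", {
  set.seed(11)
  rec <- newRecording(matrix(rnorm(3 * 50), 3, 50), fs = 50,
                      subjectId = "S7", label = "ASD",
                      channelNames = c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  saveRecording(rec, path)
  back <- loadRecording(path)
  expect_identical(recordingData(back), recordingData(rec))
  expect_identical(samplingRate(back), 50)
  expect_identical(channelNames(back), c("A", "B", "C"))
  expect_identical(subjectId(back), "S7")
  expect_identical(recordingLabel(back), "ASD")
})

test_that("malformed containers are rejected with diagnostics", {
  expect_error(loadRecording("does/not/exist.tsv"), "no such file")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ppafuse-recording v1", "#fs=10", "A\tA", "1\t2", "3\t4"),
             path)
  expect_error(loadRecording(path), "duplicate channel")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ppafuse-recording v1", "#fs=10", "A\tB", "1\tNaN"), path2)
  expect_error(loadRecording(path2), "non-finite")
  # channel/layout mismatch
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ppafuse-recording v1", "#fs=10", "A\tZ", "1\t2"), path3)
  expect_error(loadRecording(path3, sensorLayout(c("A", "B"),
                                                 c("left", "right"))),
               "absent from layout")
  expect_error(newRecording(matrix(c(1, NA), 1, 2), fs = 10),
               "finite")
})

test_that("band-pass filter stops sub-band tones and passes in-band tones", {
  t <- timeAxis(40, 200)
  slow <- toneRecording(cos(2 * pi * 0.2 * t), fs = 200)
  mid <- toneRecording(cos(2 * pi * 10 * t), fs = 200)
  rms <- function(r) sqrt(mean(recordingData(r)^2))
  expect_lt(rms(bandpassFilter(slow, 1, 99)) / rms(slow), 0.05)
  expect_equal(rms(bandpassFilter(mid, 1, 99)) / rms(mid), 1,
               tolerance = 0.05)
  expect_error(bandpassFilter(mid, 30, 30), "lo < hi")
  expect_error(bandpassFilter(mid, 50, 120), "lo < hi")
})

test_that("notch kills the target line but spares 2 Hz neighbours", {
  t <- timeAxis(20, 250)
  rms <- function(r) sqrt(mean(recordingData(r)^2))
  at50 <- toneRecording(cos(2 * pi * 50 * t), fs = 250)
  at48 <- toneRecording(cos(2 * pi * 48 * t), fs = 250)
  expect_lt(rms(notchFilter(at50, 50)) / rms(at50), 0.10)
  expect_gt(rms(notchFilter(at48, 50)) / rms(at48), 0.70)
  expect_error(notchFilter(at50, 0), "notch frequency")
})

test_that("filtering is linear within float tolerance", {
  set.seed(5)
  t <- timeAxis(10, 250)
  x <- rnorm(length(t)); y <- rnorm(length(t))
  f <- function(v) recordingData(bandpassFilter(toneRecording(v, 250),
                                                1, 100))
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
})

test_that("hemispheric channel selection keeps counts and order", {
  mon <- defaultMontage()
  rec <- newRecording(matrix(0, 151, 20,
                             dimnames = list(channelNames(mon), NULL)),
                      fs = 20)
  expect_identical(nrow(selectChannels(rec, mon, "left")@data), 70L)
  expect_identical(nrow(selectChannels(rec, mon, "right")@data), 70L)
  expect_identical(dim(selectChannels(rec, mon, "all"))[1], 151L)
  expect_error(selectChannels(rec, mon, "frontal"))
  # no-midline layout splits evenly; order preserved
  lay <- sensorLayout(c("a", "b", "c", "d"),
                      c("left", "right", "left", "right"))
  r2 <- newRecording(matrix(1:8, 4, 2,
                            dimnames = list(c("a", "b", "c", "d"), NULL)),
                     fs = 2)
  left <- selectChannels(r2, lay, "left")
  expect_identical(channelNames(left), c("a", "c"))
})

test_that("layout CSV round trip and montage invariants hold", {
  mon <- defaultMontage()
  hemi <- hemisphereOf(mon)
  expect_identical(sum(hemi == "left"), 70L)
  expect_identical(sum(hemi == "midline"), 11L)
  expect_identical(sum(hemi == "right"), 70L)
  expect_identical(length(hemi), 151L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLayout(mon, path)
  back <- readLayout(path)
  expect_identical(channelNames(back), channelNames(mon))
  expect_identical(hemisphereOf(back), hemisphereOf(mon))
  expect_error(sensorLayout(c("a", "a"), c("left", "left")), "unique")
})
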