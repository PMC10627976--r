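test_that("the fold plan reproduces the 36/12/12 stratified nested split", {
  labels <- rep(c("TD", "ASD"), each = 30)
  plan <- makeFoldPlan(labels, k = 5, seed = 42)
  for (f in plan@folds) {
    expect_length(f$train, 36)
    expect_length(f$validation, 12)
    expect_length(f$test, 12)
    for (set in f)  # 50/50 class balance inside every set
      expect_equal(sum(labels[set] == "TD"), length(set) / 2)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
  }
  tests <- unlist(lapply(plan@folds, `[[`, "test"))
  expect_identical(sort(tests), 1:60)        # exhaustive, no duplicates
  plan2 <- makeFoldPlan(labels, k = 5, seed = 42)
  expect_identical(plan@folds, plan2@folds)  # seeded determinism
  expect_false(identical(plan@folds,
                         makeFoldPlan(labels, k = 5, seed = 43)@folds))
  expect_error(makeFoldPlan(c(rep("TD", 3), rep("ASD", 30)), k = 5),
               "fewer than k")
})

test_that("metrics match brute-force confusion counts", {
  y <- rep(c("TD", "ASD"), each = 6)
  expect_equal(unname(computeMetrics(y, y)), c(100, 100, 100))
  allASD <- computeMetrics(y, rep("ASD", 12))
  expect_equal(unname(allASD), c(50, 100, 0))
  set.seed(14)
  for (i in 1:5) {
    yt <- sample(c("TD", "ASD"), 30, replace = TRUE)
    yp <- sample(c("TD", "ASD"), 30, replace = TRUE)
    tp <- sum(yt == "ASD" & yp == "ASD"); tn <- sum(yt == "TD" & yp == "TD")
    m <- computeMetrics(yt, yp)
    expect_equal(unname(m["accuracy"]), 100 * (tp + tn) / 30)
    expect_equal(unname(m["sensitivity"]), 100 * tp / sum(yt == "ASD"))
    expect_equal(unname(m["specificity"]), 100 * tn / sum(yt == "TD"))
  }
  expect_error(computeMetrics(character(0), character(0)))
})

test_that("chance level comes from the exact binomial tail", {
  # brute-force tail oracle at n = 60
  tailP <- function(k, n) sum(choose(n, k:n)) / 2^n
  kStar <- min(which(vapply(0:60, tailP, numeric(1), n = 60) <= 0.05)) - 1
  expect_equal(chanceLevel(60, 0.05), 100 * kStar / 60)
  expect_gt(chanceLevel(60, 0.05), 55)       # the often-cited ~60% regime
  expect_lt(chanceLevel(60, 0.05), 65)
  # monotone decreasing in alpha; large-n limit -> 50%
  expect_gt(chanceLevel(60, 0.01), chanceLevel(60, 0.05))
  expect_gt(chanceLevel(60, 0.05), chanceLevel(60, 0.5))
  expect_lt(chanceLevel(100000, 0.05), 51)
  expect_error(chanceLevel(60, 0))
})

test_that("threshold sweep maximizes mean validation accuracy, ties low", {
  va <- rbind(c(60, 80, 80), c(70, 90, 90))
  expect_equal(sweepPvalueThreshold(va, c(0.01, 0.02, 0.03))$threshold,
               0.02)
  expect_length(sweepPvalueThreshold(va, c(0.01, 0.02, 0.03))$meanAccuracy,
                3)
  # NA (empty selection in a fold) disqualifies a threshold
  va2 <- rbind(c(NA, 60), c(95, 60))
  expect_equal(sweepPvalueThreshold(va2, c(0.01, 0.02))$threshold, 0.02)
  expect_error(sweepPvalueThreshold(matrix(NA_real_, 2, 1), 0.01),
               "empty selections")
})

test_that("SEM matches its definition on fold vectors", {
  x <- c(80, 90, 85, 95, 100)
  expect_equal(ppafuse:::semOver(x), sd(x) / sqrt(5))
})

test_that("misclassification reports flag subjects and overlap sets", {
  sc <- data.frame(subject = rep(c("a", "b", "c"), 2),
                   pASD = c(0.9, 0.2, 0.6, 0.7, 0.4, 0.2),
                   label = rep(c("ASD", "TD", "ASD"), 2))
  rep1 <- misclassificationReport(sc)
  expect_identical(rep1$subject, c("a", "b", "c"))
  expect_equal(rep1$meanPASD, c(0.8, 0.3, 0.4))
  expect_identical(rep1$correct, c(TRUE, TRUE, FALSE))
  expect_identical(rep1$nTests, c(2L, 2L, 2L))
  # overlap: only the shared error survives the intersection
  rep2 <- rep1; rep2$correct <- c(FALSE, TRUE, FALSE)
  expect_identical(misclassificationOverlap(rep1, rep2), "c")
  expect_identical(misclassificationOverlap(rep1, rep1), "c")
  perfect <- rep1; perfect$correct <- TRUE
  expect_identical(misclassificationOverlap(rep1, perfect), character(0))
})

test_that("the experiment runner is deterministic and leakage-free", {
  g <- smallCohort("both", nPerClass = 5L, seed = 20)
  cfg <- smallConfig(seed = 20)
  res1 <- runExperiment(g, cfg)
  res2 <- runExperiment(g, cfg)
  expect_identical(res1@details$digests, res2@details$digests)
  expect_equal(experimentMetrics(res1), experimentMetrics(res2))
  m <- experimentMetrics(res1)
  expect_setequal(m$kind, c("PSD", "PPA", "featureFusion", "scoreFusion"))
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 100))
  expect_true(all(m$pThreshold %in% cfg$pGrid))
  sc <- experimentScores(res1, "PSD", "test")
  expect_identical(nrow(sc), 10L)   # every subject tested exactly once
  expect_identical(sort(unique(sc$subject)),
                   sort(vapply(g$recordings, subjectId, character(1))))

  # permuting test labels in fold 1 must change no fold-1 selection or
  # trained weight at any threshold
  plan <- res1@details$plan
  te <- plan@folds[[1]]$test
  labels <- vapply(g$recordings, recordingLabel, character(1))
  swap <- c(te[labels[te] == "TD"][1], te[labels[te] == "ASD"][1])
  recs2 <- g$recordings
  for (i in swap) {
    r <- recs2[[i]]
    recs2[[i]] <- newRecording(recordingData(r), fs = samplingRate(r),
                               subjectId = subjectId(r),
                               label = if (recordingLabel(r) == "TD")
                                 "ASD" else "TD")
  }
  res3 <- runExperiment(recs2, cfg, plan = plan)
  for (kk in c("PSD", "PPA", "featureFusion")) {
    expect_identical(res3@details$digests[[kk]]$selection[1, ],
                     res1@details$digests[[kk]]$selection[1, ])
    expect_identical(res3@details$digests[[kk]]$model[1, ],
                     res1@details$digests[[kk]]$model[1, ])
  }
})
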