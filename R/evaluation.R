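## Nested fivefold subject-exclusive cross-validation driver, metrics and
## reports. The experiment runner wires the stages: per fold, z-scoring and
## t-test ranking fitted on training subjects only, networks trained with
## validation early stopping across the p-value-threshold grid, then the
## threshold (and, for score fusion, the weight) picked on validation
## accuracy alone before test metrics are read off.

#' Build a stratified nested fold plan
#'
#' Subjects are partitioned by class into k mutually exclusive, jointly
#' exhaustive test sets; within each fold the remaining subjects are split
#' per class 3:1 into training and validation. With 60 balanced subjects
#' and k = 5 every fold has 36 training (18 + 18), 12 validation (6 + 6)
#' and 12 test (6 + 6) subjects. Remainders are distributed round-robin.
#'
#' @param labels per-subject class labels ("TD"/"ASD").
#' @param k fold count (default 5).
#' @param seed integer seed; identical seeds give identical plans.
#' @return A [FoldPlan-class].
#' @export
makeFoldPlan <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  classes <- c("TD", "ASD")
  if (!all(labels %in% classes)) stop("labels must be TD or ASD")
  for (cl in classes)
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  folds <- withLocalSeed(seed, {
    groups <- vector("list", k)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      grp <- rep(seq_len(k), length.out = length(idx))  # round-robin sizes
      for (f in seq_len(k))
        groups[[f]] <- c(groups[[f]], idx[grp == f])
    }
    lapply(seq_len(k), function(f) {
      test <- sort(groups[[f]])
      tr <- va <- integer(0)
      for (cl in classes) {
        rest <- sample(setdiff(which(labels == cl), test))
        nVal <- max(1L, round(length(rest) / 4))       # train:val = 3:1
        va <- c(va, rest[seq_len(nVal)])
        tr <- c(tr, rest[-seq_len(nVal)])
      }
      list(train = sort(tr), validation = sort(va), test = test)
    })
  })
  new("FoldPlan", k = k, folds = folds, seed = as.integer(seed))
}

setMethod("show", "FoldPlan", function(object) {
  sz <- vapply(object@folds, function(f)
    sprintf("%d/%d/%d", length(f$train), length(f$validation),
            length(f$test)), character(1))
  cat("FoldPlan: k =", object@k, "(train/validation/test:",
      paste(sz, collapse = ", "), ") seed", object@seed, "\n")
})

#' Classification metrics in percent
#'
#' Accuracy is the fraction of all subjects correctly classified;
#' sensitivity is the ASD recall, specificity the TD recall.
#'
#' @param yTrue,yPred equal-length label vectors in \{"TD", "ASD"\}.
#' @return Named numeric: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, each in [0, 100].
#' @export
computeMetrics <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) > 0,
            all(yTrue %in% c("TD", "ASD")), all(yPred %in% c("TD", "ASD")))
  acc <- 100 * mean(yTrue == yPred)
  sens <- 100 * mean(yPred[yTrue == "ASD"] == "ASD")
  spec <- 100 * mean(yPred[yTrue == "TD"] == "TD")
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Empirical chance level by exact binomial tail
#'
#' The smallest accuracy k/n (as a percentage) whose one-sided tail
#' probability under Binomial(n, 1/2) is at most alpha: the accuracy a
#' label-guessing classifier exceeds with probability < alpha. Computed by
#' exact tail summation, not a normal approximation. For n = 60 and
#' alpha = 0.05 this is just above 60%.
#'
#' @param n number of classified subjects.
#' @param alpha significance level in (0, 1).
#' @return Percentage in (50, 100].
#' @export
chanceLevel <- function(n, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  ks <- 0:n
  tail <- stats::pbinom(ks - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  k <- min(ks[tail <= alpha])
  100 * k / n
}

#' Pick a p-value threshold from fold-wise validation accuracies
#'
#' @param valAcc numeric matrix, folds x thresholds, of validation
#'   accuracies (%); NA marks an unusable threshold (empty selection in
#'   some fold).
#' @param grid the threshold grid (columns of \code{valAcc}).
#' @return List: \code{threshold} maximizing mean validation accuracy
#'   (ties to the smaller threshold), \code{meanAccuracy} per grid point.
#' @export
sweepPvalueThreshold <- function(valAcc, grid) {
  stopifnot(ncol(valAcc) == length(grid), length(grid) > 0)
  m <- colMeans(valAcc)
  m[is.na(m)] <- -Inf
  if (all(!is.finite(m)))
    stop("all thresholds yield empty selections in some fold")
  list(threshold = grid[which.max(m)], meanAccuracy = m)
}

#' Configuration for a full experiment run
#'
#' @param subset channel subset ("all", "left", "right").
#' @param scheme band scheme.
#' @param layout sensor layout (needed for hemispheric subsets).
#' @param pGrid p-value threshold grid (default 0.005..0.05 step 0.005).
#' @param weightGrid score-fusion weight grid (default 0.1..0.9 step 0.1).
#' @param ann an [AnnConfig-class] (its seed is overridden by derived
#'   per-model seeds).
#' @param k outer fold count.
#' @param seed master seed governing the fold plan and every network
#'   initialization.
#' @param nSegments,overlap Welch parameters.
#' @return A list understood by [runExperiment()].
#' @export
experimentConfig <- function(subset = "all", scheme = bandScheme(),
                             layout = NULL,
                             pGrid = seq(0.005, 0.05, by = 0.005),
                             weightGrid = seq(0.1, 0.9, by = 0.1),
                             ann = annConfig(), k = 5L, seed = 1L,
                             nSegments = 8L, overlap = 0.5) {
  list(subset = subset, scheme = scheme, layout = layout, pGrid = pGrid,
       weightGrid = weightGrid, ann = ann, k = as.integer(k),
       seed = as.integer(seed), nSegments = nSegments, overlap = overlap)
}

## Internal: train + score one (fold, feature-matrix, threshold) cell.
.fitCell <- function(X, y, fold, sel, cfgAnn, seed, subjects) {
  ann <- initialize(cfgAnn, seed = seed)
  model <- trainAnn(X[fold$train, sel, drop = FALSE], y[fold$train],
                    X[fold$validation, sel, drop = FALSE],
                    y[fold$validation], ann)
  sc <- function(rows) predictScores(model, X[rows, sel, drop = FALSE],
                                     subjects[rows])
  val <- sc(fold$validation)
  list(val = val,
       test = sc(fold$test),
       train = sc(fold$train),
       valAcc = 100 * mean(predictLabels(val) == y[fold$validation]),
       nSel = length(sel),
       modelDigest = modelDigest(model),
       selDigest = objectDigest(sel))
}

## Placeholder scores for a (fold, threshold) with an empty selection.
.emptyCell <- function(y, fold, subjects) {
  flat <- function(rows) data.frame(subject = subjects[rows],
                                    pTD = 0.5, pASD = 0.5)
  val <- flat(fold$validation)
  list(val = val, test = flat(fold$test), train = flat(fold$train),
       valAcc = 100 * mean(predictLabels(val) == y[fold$validation]),
       nSel = 0L, modelDigest = "empty", selDigest = "empty")
}

#' Run the full nested cross-validation experiment on a cohort
#'
#' Extracts PSD and PPA feature sets once, then for every fold and every
#' p-value threshold: z-score normalization fitted on training subjects,
#' t-test ranking on training subjects, network training with validation
#' early stopping, and scoring of train/validation/test subjects. The
#' operating threshold per model kind -- and, for score-level fusion, the
#' (threshold, weight) pair -- is chosen on mean validation accuracy only;
#' test metrics (mean over folds with SEM) are then reported for PSD, PPA,
#' feature-level fusion and score-level fusion. A threshold that selects no
#' feature in a fold is handled, not fatal: that fold falls back to the
#' uninformed 0.5/0.5 posterior, so over-strict thresholds on weak data
#' simply lose the validation sweep.
#'
#' @param cohort list of [Recording-class] objects (or the list returned by
#'   [generateCohort()]).
#' @param config list from [experimentConfig()].
#' @param plan optional precomputed [FoldPlan-class]; by default one is
#'   drawn from the config seed.
#' @return An [ExperimentResult-class].
#' @export
runExperiment <- function(cohort, config = experimentConfig(), plan = NULL) {
  if (!is.null(cohort$recordings)) cohort <- cohort$recordings
  labels <- vapply(cohort, recordingLabel, character(1))
  subjects <- vapply(cohort, subjectId, character(1))
  if (is.null(plan))
    plan <- makeFoldPlan(labels, config$k, deriveSeed(config$seed, 1))
  fmPsd <- extractFeatureMatrix(cohort, "PSD", config$scheme, config$layout,
                                config$subset, config$nSegments,
                                config$overlap)
  fmPpa <- extractFeatureMatrix(cohort, "PPA", config$scheme, config$layout,
                                config$subset)
  Xpsd <- featureValues(fmPsd)
  Xppa <- featureValues(fmPpa)
  y <- labels
  kinds <- c("PSD", "PPA", "featureFusion")
  nP <- length(config$pGrid)
  k <- plan@k
  cells <- lapply(kinds, function(kk)
    lapply(seq_len(k), function(f) vector("list", nP)))
  names(cells) <- kinds
  valAcc <- lapply(kinds, function(kk) matrix(NA_real_, k, nP))
  names(valAcc) <- kinds
  for (f in seq_len(k)) {
    fold <- plan@folds[[f]]
    normed <- list(
      PSD = .zapply(Xpsd, .zfit(Xpsd[fold$train, , drop = FALSE])),
      PPA = .zapply(Xppa, .zfit(Xppa[fold$train, , drop = FALSE])))
    normed$featureFusion <- cbind(normed$PSD, normed$PPA)
    for (ki in seq_along(kinds)) {
      kk <- kinds[ki]
      X <- normed[[kk]]
      tt <- .ttestMatrix(X[fold$train, , drop = FALSE], y[fold$train])
      for (pi in seq_len(nP)) {
        thr <- config$pGrid[pi]
        sel <- which(tt$p < thr)
        sel <- sel[order(tt$p[sel], sel)]
        cell <- if (length(sel)) {
          seed <- deriveSeed(config$seed, f * 1000L + ki * 100L + pi)
          .fitCell(X, y, fold, sel, config$ann, seed, subjects)
        } else {
          ## an empty selection trains nothing: the fold falls back to the
          ## uninformed 0.5/0.5 posterior (chance-level by construction)
          .emptyCell(y, fold, subjects)
        }
        cells[[kk]][[f]][[pi]] <- cell
        valAcc[[kk]][f, pi] <- cell$valAcc
      }
    }
  }

  foldMetrics <- function(kk, pi, wf = NULL) {
    t(vapply(seq_len(k), function(f) {
      fold <- plan@folds[[f]]
      sc <- if (is.null(wf)) cells[[kk]][[f]][[pi]]$test
            else fuseScores(cells$PSD[[f]][[pi]]$test,
                            cells$PPA[[f]][[pi]]$test, wf)
      computeMetrics(y[fold$test], predictLabels(sc))
    }, numeric(3)))
  }
  metricsRow <- function(kind, fm, p, w, nSel) {
    data.frame(kind = kind,
               accuracy = mean(fm[, "accuracy"]),
               accuracySem = semOver(fm[, "accuracy"]),
               sensitivity = mean(fm[, "sensitivity"]),
               sensitivitySem = semOver(fm[, "sensitivity"]),
               specificity = mean(fm[, "specificity"]),
               specificitySem = semOver(fm[, "specificity"]),
               pThreshold = p, weight = w, nSelected = nSel)
  }

  metrics <- NULL
  scores <- NULL
  chosen <- list()
  for (kk in kinds) {
    sw <- sweepPvalueThreshold(valAcc[[kk]], config$pGrid)
    pi <- match(sw$threshold, config$pGrid)
    fm <- foldMetrics(kk, pi)
    nSel <- mean(vapply(seq_len(k),
                        function(f) cells[[kk]][[f]][[pi]]$nSel, numeric(1)))
    metrics <- rbind(metrics, metricsRow(kk, fm, sw$threshold, NA_real_,
                                         nSel))
    chosen[[kk]] <- list(pIndex = pi, threshold = sw$threshold)
    for (f in seq_len(k)) {
      cell <- cells[[kk]][[f]][[pi]]
      for (set in c("test", "train")) {
        sc <- cell[[set]]
        sc$fold <- f; sc$kind <- kk; sc$set <- set
        rows <- plan@folds[[f]][[if (set == "test") "test" else "train"]]
        sc$label <- y[rows]
        scores <- rbind(scores, sc)
      }
    }
  }

  ## Score-level fusion: joint (threshold, weight) sweep on validation
  ## accuracy, reusing the already-trained PSD and PPA models.
  usable <- which(apply(!is.na(valAcc$PSD) & !is.na(valAcc$PPA), 2, all))
  if (length(usable)) {
    best <- NULL
    sweepAcc <- matrix(NA_real_, length(usable), length(config$weightGrid))
    for (ui in seq_along(usable)) {
      pi <- usable[ui]
      for (wi in seq_along(config$weightGrid)) {
        w <- config$weightGrid[wi]
        accs <- vapply(seq_len(k), function(f) {
          fold <- plan@folds[[f]]
          fused <- fuseScores(cells$PSD[[f]][[pi]]$val,
                              cells$PPA[[f]][[pi]]$val, w)
          100 * mean(predictLabels(fused) == y[fold$validation])
        }, numeric(1))
        sweepAcc[ui, wi] <- mean(accs)
        if (is.null(best) || sweepAcc[ui, wi] > best$acc + 1e-12)
          best <- list(pi = pi, w = w, acc = sweepAcc[ui, wi])
      }
    }
    fm <- foldMetrics("scoreFusion", best$pi, wf = best$w)
    nSel <- mean(vapply(seq_len(k), function(f)
      cells$PSD[[f]][[best$pi]]$nSel + cells$PPA[[f]][[best$pi]]$nSel,
      numeric(1)))
    metrics <- rbind(metrics,
                     metricsRow("scoreFusion", fm, config$pGrid[best$pi],
                                best$w, nSel))
    chosen$scoreFusion <- list(pIndex = best$pi,
                               threshold = config$pGrid[best$pi],
                               weight = best$w, sweep = sweepAcc)
    for (f in seq_len(k)) {
      sc <- fuseScores(cells$PSD[[f]][[best$pi]]$test,
                       cells$PPA[[f]][[best$pi]]$test, best$w)
      sc$fold <- f; sc$kind <- "scoreFusion"; sc$set <- "test"
      sc$label <- y[plan@folds[[f]]$test]
      scores <- rbind(scores, sc)
    }
  }

  ## Per-(fold, threshold) digests of the selected feature set and trained
  ## weights, for every kind: the substrate of leakage and determinism
  ## checks (test-set labels must not influence any of these).
  digests <- lapply(kinds, function(kk) {
    dg <- function(field) {
      m <- matrix(NA_character_, k, nP)
      for (f in seq_len(k)) for (pi in seq_len(nP)) {
        cell <- cells[[kk]][[f]][[pi]]
        if (!is.null(cell)) m[f, pi] <- cell[[field]]
      }
      m
    }
    list(model = dg("modelDigest"), selection = dg("selDigest"))
  })
  names(digests) <- kinds

  new("ExperimentResult", metrics = metrics, scores = scores,
      details = list(plan = plan, valAccuracy = valAcc, chosen = chosen,
                     digests = digests,
                     configDigest = objectDigest(config[
                       setdiff(names(config), c("scheme", "layout"))])))
}

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult\n")
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf(
      "  %-14s acc %5.1f +/- %4.2f  sens %5.1f  spec %5.1f  (p < %.3f%s, %s feat.)\n",
      m$kind[i], m$accuracy[i], m$accuracySem[i], m$sensitivity[i],
      m$specificity[i], m$pThreshold[i],
      if (is.na(m$weight[i])) "" else sprintf(", w = %.1f", m$weight[i]),
      format(m$nSelected[i])))
})

#' Metrics table of an experiment
#' @param result an [ExperimentResult-class].
#' @export
experimentMetrics <- function(result) result@metrics

#' Score table of an experiment
#' @param result an [ExperimentResult-class].
#' @param kind optional model kind filter.
#' @param set "test" or "train".
#' @export
experimentScores <- function(result, kind = NULL, set = "test") {
  s <- result@scores[result@scores$set == set, , drop = FALSE]
  if (!is.null(kind)) s <- s[s$kind == kind, , drop = FALSE]
  s
}

#' Per-subject misclassification report
#'
#' Aggregates a (possibly multi-fold, multi-repetition) test score table
#' per subject: the mean ASD score, the number of times tested, and whether
#' the subject is, on balance, misclassified.
#'
#' @param scores test score table with columns subject, pASD, label.
#' @return data.frame: subject, label, meanPASD, nTests, correct.
#' @export
misclassificationReport <- function(scores) {
  stopifnot(all(c("subject", "pASD", "label") %in% names(scores)))
  agg <- stats::aggregate(pASD ~ subject + label, scores, mean)
  n <- stats::aggregate(pASD ~ subject, scores, length)
  out <- merge(agg, n, by = "subject", suffixes = c("", ".n"))
  names(out)[names(out) == "pASD"] <- "meanPASD"
  names(out)[names(out) == "pASD.n"] <- "nTests"
  out$correct <- ifelse(out$meanPASD >= 0.5, "ASD", "TD") == out$label
  out[order(out$subject), c("subject", "label", "meanPASD", "nTests",
                            "correct")]
}

#' Subjects misclassified by both of two models
#'
#' @param reportA,reportB outputs of [misclassificationReport()].
#' @return Character vector of subjects in both error sets.
#' @export
misclassificationOverlap <- function(reportA, reportB) {
  sort(intersect(reportA$subject[!reportA$correct],
                 reportB$subject[!reportB$correct]))
}

#' Repeated reseeded experiments
#'
#' Runs R independent repetitions: each draws a fresh cohort from
#' \code{cohortFun} with a derived seed and runs the full pipeline with
#' that seed. Used for the stochastic calibration / dominance checks and
#' the complementarity histogram.
#'
#' @param nReps repetition count.
#' @param cohortFun function(seed) returning a cohort.
#' @param config base [experimentConfig()]; its seed is the master seed.
#' @return List with \code{metrics} (row-bound with a \code{rep} column)
#'   and \code{complementarity} (the training-score correlation per
#'   repetition between the PSD and PPA models).
#' @export
runRepeatedExperiment <- function(nReps, cohortFun,
                                  config = experimentConfig()) {
  metrics <- NULL
  psdTrain <- ppaTrain <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    seed <- deriveSeed(config$seed, 7000L + r)
    cfg <- config
    cfg$seed <- seed
    res <- runExperiment(cohortFun(seed), cfg)
    m <- experimentMetrics(res)
    m$rep <- r
    metrics <- rbind(metrics, m)
    ord <- function(s) s[order(s$fold, s$subject), ]
    psdTrain[[r]] <- ord(experimentScores(res, "PSD", "train"))$pASD
    ppaTrain[[r]] <- ord(experimentScores(res, "PPA", "train"))$pASD
  }
  list(metrics = metrics,
       complementarity = complementarityCheck(psdTrain, ppaTrain))
}
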