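## Score-level fusion and the complementarity criterion. Score tables are
## plain data frames with columns subject, (optionally fold), pTD, pASD.

checkScoreTable <- function(s) {
  stopifnot(is.data.frame(s), all(c("subject", "pTD", "pASD") %in% names(s)))
  if (any(s$pTD < -1e-9) || any(s$pASD < -1e-9) ||
      any(abs(s$pTD + s$pASD - 1) > 1e-6))
    stop("score rows must be probabilities summing to 1")
  s
}

matchScoreTables <- function(a, b) {
  keys <- function(s) if ("fold" %in% names(s))
    paste(s$subject, s$fold) else s$subject
  if (!identical(keys(a), keys(b)))
    stop("score tables do not cover the same subjects/folds in order")
  invisible(NULL)
}

#' Weighted score-level fusion
#'
#' Convex combination of two models' posterior score tables: fused
#' P(class) = w * P_psd(class) + (1 - w) * P_ppa(class), rowwise per
#' subject (and fold). Rows still sum to 1 and every fused score lies
#' between the two inputs.
#'
#' @param scoresPsd,scoresPpa score tables over the same subjects/folds in
#'   the same order.
#' @param w weight of the PSD model, in [0, 1].
#' @return A fused score table.
#' @examples
#' a <- data.frame(subject = "s1", pTD = 0.5, pASD = 0.5)
#' b <- data.frame(subject = "s1", pTD = 0.1, pASD = 0.9)
#' fuseScores(a, b, 0.2)$pASD   # 0.82
#' @export
fuseScores <- function(scoresPsd, scoresPpa, w) {
  stopifnot(length(w) == 1L, w >= 0, w <= 1)
  checkScoreTable(scoresPsd); checkScoreTable(scoresPpa)
  matchScoreTables(scoresPsd, scoresPpa)
  out <- scoresPsd
  out$pTD <- w * scoresPsd$pTD + (1 - w) * scoresPpa$pTD
  out$pASD <- w * scoresPsd$pASD + (1 - w) * scoresPpa$pASD
  if ("kind" %in% names(out)) out$kind <- "fused"
  out
}

#' Choose the fusion weight on validation scores
#'
#' Evaluates every weight in the grid by the accuracy of the fused
#' validation scores and returns the maximizer; ties go to the earliest
#' grid element.
#'
#' @param scoresPsd,scoresPpa validation score tables (same subjects/folds,
#'   same order).
#' @param labels true labels aligned with the table rows.
#' @param grid candidate weights (default 0.1..0.9 step 0.1).
#' @return List with \code{weight}, the full \code{grid} and per-weight
#'   \code{accuracy} (%).
#' @export
sweepFusionWeight <- function(scoresPsd, scoresPpa, labels,
                              grid = seq(0.1, 0.9, by = 0.1)) {
  if (!length(grid)) stop("empty weight grid")
  acc <- vapply(grid, function(w) {
    fused <- fuseScores(scoresPsd, scoresPpa, w)
    100 * mean(predictLabels(fused) == labels)
  }, numeric(1))
  list(weight = grid[which.max(acc)], grid = grid, accuracy = acc)
}

#' Complementarity of two models' training scores
#'
#' Two feature types are worth fusing when their classifiers make
#' uncorrelated errors; the criterion is the Pearson correlation between
#' the two models' per-subject training ASD scores, computed once per
#' repetition (one reseeded cross-validation run each), with the mean over
#' repetitions reported. Values near 0 license fusion; near 1 the models
#' are redundant; near -1 they are antagonistic. Repetitions with a
#' constant score vector (undefined correlation) are skipped and counted.
#'
#' @param psdScores,ppaScores either numeric vectors (one repetition) or
#'   lists of numeric vectors (one per repetition); paired per subject.
#' @return List: \code{coefficients} (one per usable repetition),
#'   \code{mean}, \code{skipped} count.
#' @export
complementarityCheck <- function(psdScores, ppaScores) {
  if (is.numeric(psdScores)) psdScores <- list(psdScores)
  if (is.numeric(ppaScores)) ppaScores <- list(ppaScores)
  stopifnot(length(psdScores) == length(ppaScores))
  coefs <- numeric(0); skipped <- 0L
  for (i in seq_along(psdScores)) {
    a <- psdScores[[i]]; b <- ppaScores[[i]]
    stopifnot(length(a) == length(b), length(a) >= 2L)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      skipped <- skipped + 1L
      next
    }
    coefs <- c(coefs, stats::cor(a, b))
  }
  list(coefficients = coefs,
       mean = if (length(coefs)) mean(coefs) else NA_real_,
       skipped = skipped)
}
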