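## Feature normalization and t-test ranking. The public API works on
## FeatureSet objects and explicit row (subject) index sets so that fitting
## can be restricted to training subjects; matrix-level internals are shared
## with the cross-validation driver.

## ---- z-scoring ------------------------------------------------------------

.zfit <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  constant <- !is.finite(s) | s == 0
  s[constant] <- 1
  list(mean = m, sd = s, constant = constant)
}

.zapply <- function(X, pars) {
  sweep(sweep(X, 2L, pars$mean, "-"), 2L, pars$sd, "/")
}

#' Fit per-feature z-score parameters on a subject subset
#'
#' Means and sample standard deviations are computed over the fit rows only
#' (typically the training subjects of a fold) and can then be applied to
#' any rows, so held-out subjects never influence the normalization.
#' Constant features get sd := 1 and are flagged.
#'
#' @param fm a [FeatureSet-class].
#' @param fitRows integer subject indices to fit on (default: all).
#' @return List with \code{mean}, \code{sd}, logical \code{constant}.
#' @examples
#' # a feature column c(1, 2, 3) fits to mean 2, sd 1
#' @export
zscoreFit <- function(fm, fitRows = seq_len(ncol(fm))) {
  if (!length(fitRows)) stop("empty fit set")
  if (length(fitRows) < 2L) stop("need at least 2 rows to fit a z-score")
  .zfit(featureValues(fm)[fitRows, , drop = FALSE])
}

#' Apply fitted z-score parameters to every subject
#'
#' @param fm a [FeatureSet-class].
#' @param pars parameters from [zscoreFit()].
#' @return A [FeatureSet-class] with normalized values.
#' @export
zscoreApply <- function(fm, pars) {
  setFeatureValues(fm, .zapply(featureValues(fm), pars))
}

## ---- t-test ranking -------------------------------------------------------

## Vectorized pooled-variance two-sample t over feature columns.
## X: subjects x features; y: labels ("TD"/"ASD"). Returns t and two-sided p.
.ttestMatrix <- function(X, y) {
  g1 <- y == "TD"
  g2 <- y == "ASD"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per class")
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[g2, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0   # constant-in-both-classes features carry no signal
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  list(t = t, p = p)
}

#' Rank features by a two-sample t-test
#'
#' Pooled-variance (Student) two-sided t statistic and p-value per feature
#' between the TD and ASD subjects among the given rows only -- held-out
#' subjects are never touched, which is what makes per-fold selection
#' leakage-free. PPA angles are treated as linear reals, as the feature
#' pipeline defines them.
#'
#' @param fm a [FeatureSet-class].
#' @param rows subject indices to test over (default: all).
#' @param var.equal pooled variance (default TRUE, the classical t-test);
#'   FALSE switches to Welch's approximation.
#' @return A [SelectionResult-class] with t statistics and p-values
#'   (threshold not yet applied).
#' @export
ttestRank <- function(fm, rows = seq_len(ncol(fm)), var.equal = TRUE) {
  X <- featureValues(fm)[rows, , drop = FALSE]
  y <- subjectLabels(fm)[rows]
  if (!all(c("TD", "ASD") %in% y)) stop("both classes must be present")
  if (var.equal) {
    res <- .ttestMatrix(X, y)
  } else {
    res <- list(t = numeric(ncol(X)), p = numeric(ncol(X)))
    for (j in seq_len(ncol(X))) {
      tt <- stats::t.test(X[y == "TD", j], X[y == "ASD", j],
                          var.equal = FALSE)
      res$t[j] <- unname(tt$statistic); res$p[j] <- tt$p.value
    }
  }
  new("SelectionResult", tStats = unname(res$t), pValues = unname(res$p),
      threshold = NA_real_, selectedIndices = integer())
}

#' Select features below a p-value threshold
#'
#' Keeps exactly the features with p < threshold, ordered by ascending
#' p-value with ties broken by ascending column index.
#'
#' @param sel a [SelectionResult-class] from [ttestRank()].
#' @param threshold p-value threshold in (0, 1).
#' @return A [SelectionResult-class] with \code{threshold} and
#'   \code{selectedIndices} filled. The selection may be empty; downstream
#'   consumers must handle that.
#' @export
selectByThreshold <- function(sel, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  idx <- which(sel@pValues < threshold)
  idx <- idx[order(sel@pValues[idx], idx)]
  initialize(sel, threshold = threshold, selectedIndices = as.integer(idx))
}

#' Number of selected features
#' @param sel a [SelectionResult-class].
#' @export
selectedCount <- function(sel) length(sel@selectedIndices)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@pValues), "features ranked;",
      if (is.na(object@threshold)) "no threshold applied"
      else paste0(selectedCount(object), " selected at p < ",
                  object@threshold), "\n")
})
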