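#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SensorLayout: hemisphere assignment of a channel montage
#'
#' A montage is the ordered list of channel names together with a
#' left / midline / right hemisphere tag per channel. Hemispheric feature
#' sets drop the midline channels and keep one hemisphere, preserving order.
#'
#' @slot channelNames character vector of unique channel names.
#' @slot hemisphere character vector, one of \code{"left"}, \code{"midline"},
#'   \code{"right"} per channel.
#' @seealso [sensorLayout()], [defaultMontage()], [deskMontage()]
#' @export
setClass("SensorLayout",
  representation(channelNames = "character", hemisphere = "character"))

setValidity("SensorLayout", function(object) {
  if (length(object@channelNames) != length(object@hemisphere))
    return("channelNames and hemisphere must have equal length")
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  bad <- setdiff(unique(object@hemisphere), c("left", "midline", "right"))
  if (length(bad))
    return(paste0("unknown hemisphere tag(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Recording: one subject's multichannel time series
#'
#' Holds a channels x samples real matrix at a fixed sampling rate, with the
#' subject identifier and (optionally) the class label. Channel names are the
#' row names of the data matrix.
#'
#' @slot subjectId length-1 character.
#' @slot data numeric matrix, channels in rows, samples in columns; all values
#'   finite. Row names are the channel names.
#' @slot fs sampling rate in Hz.
#' @slot label class label, one of \code{"TD"}, \code{"ASD"},
#'   \code{"unknown"}.
#' @seealso [newRecording()], [loadRecording()], [bandpassFilter()]
#' @export
setClass("Recording",
  representation(subjectId = "character", data = "matrix", fs = "numeric",
                 label = "character"))

setValidity("Recording", function(object) {
  if (length(object@subjectId) != 1L) return("subjectId must be length 1")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (is.null(rownames(object@data)))
    return("data must carry channel names as row names")
  if (anyDuplicated(rownames(object@data)))
    return("channel names must be unique")
  if (!is.numeric(object@data) || anyNA(object@data) ||
      !all(is.finite(object@data)))
    return("data must be a finite numeric matrix")
  if (ncol(object@data) < 1L) return("recording has no samples")
  if (!(object@label %in% validLabels))
    return("label must be one of TD, ASD, unknown")
  TRUE
})

#' SpectrumSet: per-channel power and/or phase on the 1--100 Hz integer grid
#'
#' Power is the one-sided Welch spectral density S(f) sampled at the integer
#' frequencies 1..100 Hz; phase is the full-record DFT phase angle theta(f) in
#' (-pi, pi] on the same grid. Either component may be absent (a 0 x 0
#' matrix) when only one was computed.
#'
#' @slot power numeric matrix channels x 100 (or 0 x 0), non-negative.
#' @slot phase numeric matrix channels x 100 (or 0 x 0), radians in
#'   (-pi, pi].
#' @seealso [welchSpectrum()], [fftPhases()], [computeSpectra()]
#' @export
setClass("SpectrumSet",
  representation(power = "matrix", phase = "matrix"))

setValidity("SpectrumSet", function(object) {
  chkGrid <- function(m, what) {
    if (nrow(m) == 0L && ncol(m) == 0L) return(NULL)
    if (ncol(m) != 100L)
      return(paste(what, "must have 100 columns (1..100 Hz integer grid)"))
    if (anyNA(m) || !all(is.finite(m)))
      return(paste(what, "must be finite"))
    NULL
  }
  err <- chkGrid(object@power, "power")
  if (!is.null(err)) return(err)
  err <- chkGrid(object@phase, "phase")
  if (!is.null(err)) return(err)
  if (ncol(object@power) && any(object@power < 0))
    return("power must be non-negative")
  if (ncol(object@phase) &&
      (any(object@phase <= -pi - 1e-12) || any(object@phase > pi + 1e-12)))
    return("phase must lie in (-pi, pi]")
  if (ncol(object@power) && ncol(object@phase) &&
      nrow(object@power) != nrow(object@phase))
    return("power and phase must cover the same channels")
  TRUE
})

#' FeatureSet: subjects x spectral features as a SummarizedExperiment
#'
#' Stored Bioconductor-style with features in rows and subjects in columns.
#' \code{rowData} carries the feature descriptors (\code{channel},
#' \code{band}, \code{kind} in \{PSD, PPA\}); \code{colData} carries
#' \code{subject} and \code{label}; \code{metadata(x)$kindTag} is one of
#' \code{"PSD"}, \code{"PPA"}, \code{"fused"}.
#'
#' @seealso [extractFeatureMatrix()], [featureValues()], [fuseFeatures()]
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  rd <- rowData(object)
  need <- c("channel", "band", "kind")
  if (!all(need %in% colnames(rd)))
    return("rowData must have columns channel, band, kind")
  if (!all(rd$kind %in% c("PSD", "PPA")))
    return("feature kind must be PSD or PPA")
  cd <- colData(object)
  if (!all(c("subject", "label") %in% colnames(cd)))
    return("colData must have columns subject, label")
  if (!all(cd$label %in% validLabels))
    return("labels must be TD, ASD or unknown")
  tag <- S4Vectors::metadata(object)$kindTag
  if (is.null(tag) || !(tag %in% c("PSD", "PPA", "fused")))
    return("metadata kindTag must be PSD, PPA or fused")
  TRUE
})

#' SelectionResult: t-test ranking of features with an optional threshold
#'
#' @slot tStats per-feature two-sample t statistic.
#' @slot pValues per-feature two-sided p-value.
#' @slot threshold the p-value threshold applied (NA before
#'   [selectByThreshold()]).
#' @slot selectedIndices feature column indices with p < threshold, ordered
#'   by ascending p (ties by ascending index).
#' @seealso [ttestRank()], [selectByThreshold()]
#' @export
setClass("SelectionResult",
  representation(tStats = "numeric", pValues = "numeric",
                 threshold = "numeric", selectedIndices = "integer"))

setValidity("SelectionResult", function(object) {
  if (length(object@tStats) != length(object@pValues))
    return("tStats and pValues must have equal length")
  p <- object@pValues
  if (length(p) && (any(p < 0) || any(p > 1))) return("p-values outside [0,1]")
  if (any(object@selectedIndices < 1L) ||
      any(object@selectedIndices > length(p)))
    return("selectedIndices out of range")
  TRUE
})

#' AnnConfig: feedforward network hyperparameters
#'
#' Defaults mirror the fixed study configuration: 10 tanh hidden units, two
#' softmax output units, at most 10000 full-batch epochs, a training MSE goal
#' of 1e-5, and early stopping after 6 consecutive validation-error
#' increases, returning the minimum-validation-error weights.
#'
#' @slot hiddenUnits number of tanh hidden units.
#' @slot maxEpochs epoch cap.
#' @slot goalMse training mean squared error at which training stops.
#' @slot patience consecutive validation-error increases tolerated.
#' @slot seed integer seed for weight initialization.
#' @seealso [annConfig()], [trainAnn()]
#' @export
setClass("AnnConfig",
  representation(hiddenUnits = "integer", maxEpochs = "integer",
                 goalMse = "numeric", patience = "integer", seed = "integer"))

setValidity("AnnConfig", function(object) {
  if (object@hiddenUnits < 1L) return("hiddenUnits must be >= 1")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@goalMse <= 0) return("goalMse must be positive")
  TRUE
})

#' TrainedModel: fitted network weights plus training trace
#'
#' @slot weights list with elements W1, b1, W2, b2 (the
#'   minimum-validation-error weights).
#' @slot trace list: epochs run, per-epoch train/validation MSE, best epoch.
#' @slot config the [AnnConfig-class] used.
#' @seealso [trainAnn()], [predictScores()]
#' @export
setClass("TrainedModel",
  representation(weights = "list", trace = "list", config = "AnnConfig"))

#' FoldPlan: subject-exclusive nested cross-validation partition
#'
#' For each of the k folds, disjoint train / validation / test subject-index
#' sets; the k test sets are mutually exclusive and together cover every
#' subject. Construction is stratified by class.
#'
#' @slot k fold count.
#' @slot folds list of k lists with integer elements \code{train},
#'   \code{validation}, \code{test}.
#' @slot seed the seed the plan was drawn with.
#' @seealso [makeFoldPlan()]
#' @export
setClass("FoldPlan",
  representation(k = "integer", folds = "list", seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (length(object@folds) != object@k) return("folds list must have k elements")
  tests <- lapply(object@folds, `[[`, "test")
  all_test <- unlist(tests)
  if (anyDuplicated(all_test)) return("test sets must be mutually exclusive")
  for (f in object@folds) {
    ids <- c(f$train, f$validation, f$test)
    if (anyDuplicated(ids))
      return("train/validation/test must be disjoint within a fold")
  }
  TRUE
})

#' EffectSpec: class-conditional oscillatory effect for the cohort generator
#'
#' Per frequency band: a sinusoid amplitude, a von Mises preferred angle mu
#' and concentration kappa governing the per-(channel, frequency-bin) phase
#' draws; plus the white-noise standard deviation and the set of affected
#' channels. Unaffected channels are pure noise.
#'
#' @slot scheme band scheme data frame (see [bandScheme()]).
#' @slot amplitude named numeric, sinusoid amplitude per band (>= 0).
#' @slot mu named numeric, preferred phase angle per band (radians).
#' @slot kappa named numeric, von Mises concentration per band (>= 0; 0 means
#'   uniform phases).
#' @slot noiseSd white Gaussian noise standard deviation.
#' @slot affectedChannels integer channel indices carrying the oscillations.
#' @seealso [effectSpec()], [generateRecording()], [cohortPreset()]
#' @export
setClass("EffectSpec",
  representation(scheme = "data.frame", amplitude = "numeric", mu = "numeric",
                 kappa = "numeric", noiseSd = "numeric",
                 affectedChannels = "integer"))

setValidity("EffectSpec", function(object) {
  nb <- nrow(object@scheme)
  for (s in c("amplitude", "mu", "kappa")) {
    v <- slot(object, s)
    if (length(v) != nb)
      return(paste(s, "must have one value per band"))
  }
  if (any(object@amplitude < 0)) return("amplitudes must be >= 0")
  if (any(object@kappa < 0)) return("kappa must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' ExperimentResult: metrics, score tables and per-fold details of one run
#'
#' @slot metrics data frame, one row per model kind (PSD, PPA, featureFusion,
#'   scoreFusion): accuracy / sensitivity / specificity each with SEM (%),
#'   chosen p-threshold, chosen fusion weight, mean selected-feature count.
#' @slot scores score table (data frame: subject, fold, kind, pTD, pASD,
#'   label, set) for test and training subjects at the chosen operating
#'   points.
#' @slot details list of per-kind grids, selections and weight digests.
#' @seealso [runExperiment()]
#' @export
setClass("ExperimentResult",
  representation(metrics = "data.frame", scores = "data.frame",
                 details = "list"))
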