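#' @describeIn FeatureSet-class the subjects x features value matrix (the
#'   transposed assay, the orientation selection and classification work in).
#' @param x a [FeatureSet-class]
#' @export
setMethod("featureValues", "FeatureSet", function(x) t(assay(x, "features")))

#' @describeIn FeatureSet-class per-subject class labels.
#' @export
setMethod("subjectLabels", "FeatureSet", function(x) {
  stats::setNames(colData(x)$label, colData(x)$subject)
})

#' @describeIn FeatureSet-class per-feature descriptors (channel, band,
#'   kind).
#' @export
setMethod("featureInfo", "FeatureSet", function(x) rowData(x))

#' @describeIn FeatureSet-class the set-level tag: PSD, PPA or fused.
#' @export
setMethod("kindTag", "FeatureSet", function(x) {
  S4Vectors::metadata(x)$kindTag
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet [", S4Vectors::metadata(object)$kindTag, "]: ",
      ncol(object), " subjects x ", nrow(object), " features (",
      paste(names(table(colData(object)$label)),
            table(colData(object)$label), sep = ":", collapse = ", "),
      ")\n", sep = "")
})

## Replace the assay values of a FeatureSet, keeping annotation.
setFeatureValues <- function(fm, values) {
  stopifnot(identical(dim(values), dim(t(assay(fm, "features")))))
  a <- t(values)
  dimnames(a) <- dimnames(assay(fm, "features"))
  SummarizedExperiment::assay(fm, "features") <- a
  fm
}

#' Feature-level fusion by column concatenation
#'
#' Concatenates two feature sets over the same subjects (PSD columns first),
#' preserving each feature's origin kind in the descriptors. Both inputs are
#' expected to be normalized already; the fused matrix is then re-submitted
#' to feature selection downstream.
#'
#' @param fmPsd,fmPpa [FeatureSet-class] objects with identical subjects in
#'   identical order.
#' @return A fused [FeatureSet-class] with \code{kindTag(x) == "fused"}.
#' @export
fuseFeatures <- function(fmPsd, fmPpa) {
  if (!identical(colData(fmPsd)$subject, colData(fmPpa)$subject))
    stop("subject sets/order differ between the two feature sets")
  if (!identical(colData(fmPsd)$label, colData(fmPpa)$label))
    stop("labels differ between the two feature sets")
  vals <- rbind(assay(fmPsd, "features"), assay(fmPpa, "features"))
  desc <- rbind(rowData(fmPsd), rowData(fmPpa))
  se <- SummarizedExperiment(
    assays = list(features = vals), rowData = desc,
    colData = colData(fmPsd), metadata = list(kindTag = "fused"))
  new("FeatureSet", se)
}

#' Write / read a feature set as CSV
#'
#' Subjects in rows: \code{subject}, \code{label}, then one column per
#' feature named \code{channel.band.kind}.
#'
#' @param fm a [FeatureSet-class].
#' @param path file path.
#' @return \code{writeFeatureCsv} returns \code{path} invisibly.
#' @export
writeFeatureCsv <- function(fm, path) {
  v <- featureValues(fm)
  df <- data.frame(subject = colData(fm)$subject, label = colData(fm)$label,
                   v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
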