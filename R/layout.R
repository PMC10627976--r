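#' Construct a sensor layout
#'
#' @param channelNames character vector of unique channel names.
#' @param hemisphere per-channel tag, \code{"left"}, \code{"midline"} or
#'   \code{"right"}.
#' @return A [SensorLayout-class].
#' @examples
#' sensorLayout(c("L1", "M1", "R1"), c("left", "midline", "right"))
#' @export
sensorLayout <- function(channelNames, hemisphere) {
  new("SensorLayout", channelNames = as.character(channelNames),
      hemisphere = as.character(hemisphere))
}

#' Build a left/midline/right montage with the given channel counts
#'
#' Channel names are generated as \code{L001..}, \code{M01..}, \code{R001..}
#' in left, midline, right order.
#'
#' @param nLeft,nMidline,nRight channel counts per region.
#' @return A [SensorLayout-class].
#' @export
makeMontage <- function(nLeft, nMidline, nRight) {
  nm <- c(sprintf("L%03d", seq_len(nLeft)),
          sprintf("M%02d", seq_len(nMidline)),
          sprintf("R%03d", seq_len(nRight)))
  sensorLayout(nm, rep(c("left", "midline", "right"),
                       c(nLeft, nMidline, nRight)))
}

#' The default 151-channel montage
#'
#' The whole-head child-MEG montage geometry used throughout: 70 left, 11
#' midline and 70 right sensors (151 channels total). The vendor's exact
#' sensor positions are not bundled; only the hemisphere partition matters
#' for feature extraction, and this synthetic montage reproduces it.
#'
#' @return A [SensorLayout-class] with 151 channels.
#' @examples
#' length(channelNames(defaultMontage()))
#' @export
defaultMontage <- function() makeMontage(70L, 11L, 70L)

#' A small desk-scale montage for simulation
#'
#' 20 channels (9 left, 2 midline, 9 right), the default geometry of the
#' synthetic cohort generator.
#'
#' @param nChannels total channel count; midline gets
#'   \code{max(0, nChannels - 2 * floor(nChannels / 2))} plus an even
#'   left/right split of the remainder.
#' @return A [SensorLayout-class].
#' @export
deskMontage <- function(nChannels = 20L) {
  nSide <- (nChannels - nChannels %% 2L) %/% 2L
  nMid <- nChannels - 2L * nSide
  if (nMid == 0L && nSide >= 1L) {   # carve a 2-channel midline when room
    if (nSide > 2L) { nSide <- nSide - 1L; nMid <- 2L }
  }
  makeMontage(nSide, nMid, nSide)
}

#' @describeIn SensorLayout-class channel names of the montage.
#' @export
setMethod("channelNames", "SensorLayout", function(x) x@channelNames)

#' Hemisphere tags of a layout
#' @param layout a [SensorLayout-class].
#' @return Character vector of per-channel tags.
#' @export
hemisphereOf <- function(layout) {
  stats::setNames(layout@hemisphere, layout@channelNames)
}

#' Read / write a sensor layout as CSV
#'
#' The file has columns \code{channel,hemisphere}.
#'
#' @param path file path.
#' @return \code{readLayout} returns a [SensorLayout-class];
#'   \code{writeLayout} returns \code{path} invisibly.
#' @export
readLayout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "hemisphere") %in% names(df)))
    stop("layout CSV must have columns channel,hemisphere")
  sensorLayout(df$channel, df$hemisphere)
}

#' @rdname readLayout
#' @param layout a [SensorLayout-class] to write.
#' @export
writeLayout <- function(layout, path) {
  utils::write.csv(
    data.frame(channel = layout@channelNames,
               hemisphere = layout@hemisphere),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

setMethod("show", "SensorLayout", function(object) {
  tab <- table(factor(object@hemisphere,
                      levels = c("left", "midline", "right")))
  cat("SensorLayout with", length(object@channelNames), "channels (",
      tab[["left"]], "left /", tab[["midline"]], "midline /",
      tab[["right"]], "right )\n")
})
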