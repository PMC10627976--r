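#' Construct a Recording
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param channelNames channel names; defaults to existing row names.
#' @param label class label (\code{"TD"}, \code{"ASD"} or \code{"unknown"}).
#' @return A [Recording-class].
#' @examples
#' r <- newRecording(matrix(rnorm(200), 2, 100), fs = 100, subjectId = "S1")
#' duration(r)
#' @export
newRecording <- function(data, fs, subjectId = "anon",
                         channelNames = rownames(data),
                         label = "unknown") {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- sprintf("ch%03d", seq_len(nrow(data)))
  rownames(data) <- channelNames
  new("Recording", subjectId = as.character(subjectId), data = data,
      fs = as.numeric(fs), label = as.character(label))
}

#' @describeIn Recording-class channel names.
#' @export
setMethod("channelNames", "Recording", function(x) rownames(x@data))

#' @describeIn Recording-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @describeIn Recording-class subject identifier.
#' @export
setMethod("subjectId", "Recording", function(x) x@subjectId)

#' @describeIn Recording-class class label.
#' @export
setMethod("recordingLabel", "Recording", function(x) x@label)

#' @describeIn Recording-class the channels x samples data matrix.
#' @export
setMethod("recordingData", "Recording", function(x) x@data)

#' @describeIn Recording-class channels x samples dimensions.
#' @export
setMethod("dim", "Recording", function(x) dim(x@data))

#' Recording duration in seconds
#' @param x a [Recording-class].
#' @export
duration <- function(x) ncol(x@data) / x@fs

setMethod("show", "Recording", function(object) {
  cat("Recording", object@subjectId, "(", object@label, "):",
      nrow(object@data), "channels x", ncol(object@data), "samples @",
      object@fs, "Hz (", format(duration(object), digits = 4), "s )\n")
})

## ---- on-disk container ----------------------------------------------------

#' Save / load a recording as a self-describing text container
#'
#' The native on-disk form is a tab-separated text file: '#key=value' header
#' lines carrying \code{fs}, \code{subject_id} and \code{label}, a channel
#' name header row, then samples in rows (channels as columns). Values are
#' written at full precision so a save/load round trip is bit-identical.
#'
#' @param rec a [Recording-class].
#' @param path file path.
#' @return \code{saveRecording} returns \code{path} invisibly;
#'   \code{loadRecording} returns a [Recording-class].
#' @export
saveRecording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#ppafuse-recording v1",
               paste0("#subject_id=", rec@subjectId),
               paste0("#fs=", format(rec@fs, digits = 17)),
               paste0("#label=", rec@label),
               paste(rownames(rec@data), collapse = "\t")), con)
  utils::write.table(
    format(t(rec@data), digits = 17, trim = TRUE, scientific = TRUE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saveRecording
#' @param layout optional [SensorLayout-class]; when given, the file's
#'   channel names must all be present in the layout.
#' @export
loadRecording <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head <- readLines(path, n = 16L)
  meta <- head[startsWith(head, "#")]
  kv <- sub("^#", "", meta[grepl("=", meta, fixed = TRUE)])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  getf <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  fs <- getf("fs")
  if (is.null(fs)) stop("container lacks an fs attribute: ", path)
  nameLine <- head[!startsWith(head, "#")][1]
  chn <- strsplit(nameLine, "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(chn))
    stop("duplicate channel name(s) in ", path, ": ",
         paste(unique(chn[duplicated(chn)]), collapse = ", "))
  body <- utils::read.table(path, sep = "\t", comment.char = "#",
                            header = TRUE, check.names = FALSE,
                            colClasses = "numeric")
  mat <- t(as.matrix(body))
  rownames(mat) <- chn
  if (anyNA(mat) || !all(is.finite(mat)))
    stop("non-finite samples in ", path)
  if (!is.null(layout)) {
    missing <- setdiff(chn, layout@channelNames)
    if (length(missing))
      stop("channels absent from layout: ", paste(missing, collapse = ", "))
  }
  newRecording(mat, fs = as.numeric(fs),
               subjectId = getf("subject_id", "anon"),
               channelNames = chn,
               label = getf("label", "unknown"))
}

## ---- filtering ------------------------------------------------------------

## Zero-phase (forward-backward) filtering of every channel.
applyFiltfilt <- function(rec, b, a) {
  out <- t(apply(rec@data, 1L, function(x) signal::filtfilt(b, a, x)))
  rownames(out) <- rownames(rec@data)
  newRecording(out, fs = rec@fs, subjectId = rec@subjectId,
               label = rec@label)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero group delay) filtering with a 4th-order
#' Butterworth band-pass design. Zero-phase filtering is essential here:
#' any group delay would rotate the Fourier phases that the preferred phase
#' angle is computed from.
#'
#' @param rec a [Recording-class].
#' @param lo,hi band edges in Hz, \code{0 < lo < hi < fs/2}.
#' @param order Butterworth order of the one-way design (default 4; the
#'   two-pass response has twice the rolloff).
#' @return A filtered [Recording-class] with identical geometry.
#' @export
bandpassFilter <- function(rec, lo, hi, order = 4L) {
  fs <- rec@fs
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2 (fs = ", fs, ")")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  applyFiltfilt(rec, bf$b, bf$a)
}

#' Zero-phase notch filter
#'
#' A second-order IIR notch (unit-circle zeros at the target frequency,
#' poles set by the -3 dB bandwidth), applied forward-backward. With the
#' default 2 Hz bandwidth the two-pass response removes the target line
#' (> 20 dB) while integer neighbours 2 Hz away lose under 3 dB.
#'
#' @param rec a [Recording-class].
#' @param f0 notch frequency in Hz, \code{0 < f0 < fs/2} (e.g. 50 for
#'   power-line interference).
#' @param bandwidth -3 dB width of the one-way notch in Hz.
#' @return A filtered [Recording-class].
#' @export
notchFilter <- function(rec, f0, bandwidth = 2) {
  fs <- rec@fs
  if (!(f0 > 0 && f0 < fs / 2))
    stop("notch frequency must satisfy 0 < f0 < fs/2 (fs = ", fs, ")")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * bandwidth / (2 * f0)   # = sin(w0) / (2 Q), Q = f0 / bw
  ## biquad notch (zeros on the unit circle at f0), normalized to a0 = 1
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  applyFiltfilt(rec, b, a)
}

#' Restrict a recording to one hemisphere
#'
#' \code{subset = "all"} returns the recording unchanged; \code{"left"} /
#' \code{"right"} drop the midline channels and keep only that hemisphere's
#' channels, preserving their original order.
#'
#' @param rec a [Recording-class].
#' @param layout a [SensorLayout-class] covering the recording's channels.
#' @param subset \code{"all"}, \code{"left"} or \code{"right"}.
#' @return A [Recording-class].
#' @examples
#' dim(selectChannels(
#'   newRecording(matrix(0, 151, 10, dimnames = list(
#'     channelNames(defaultMontage()), NULL)), fs = 10),
#'   defaultMontage(), "left"))[1]   # 70
#' @export
selectChannels <- function(rec, layout, subset = c("all", "left", "right")) {
  subset <- match.arg(subset)
  if (subset == "all") return(rec)
  hemi <- hemisphereOf(layout)
  chn <- channelNames(rec)
  missing <- setdiff(chn, names(hemi))
  if (length(missing))
    stop("channels absent from layout: ", paste(missing, collapse = ", "))
  keep <- chn[hemi[chn] == subset]
  if (!length(keep)) stop("no channels in subset '", subset, "'")
  newRecording(rec@data[keep, , drop = FALSE], fs = rec@fs,
               subjectId = rec@subjectId, label = rec@label)
}
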