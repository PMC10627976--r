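#' The canonical six-band scheme on the 1--100 Hz integer grid
#'
#' delta (1--4), theta (4--8), alpha (8--13), beta (13--30), low gamma
#' (30--50) and high gamma (50--100 Hz). Band endpoints are inclusive on
#' both sides, so e.g. alpha covers the 6 integer bins 8..13 and boundary
#' bins (4, 8, 13, 30, 50 Hz) belong to both adjacent bands.
#'
#' @return data frame with columns \code{band}, \code{lo}, \code{hi}.
#' @examples
#' s <- bandScheme(); s$hi - s$lo + 1   # bins per band; alpha has 6
#' @export
bandScheme <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo = c(1L, 4L, 8L, 13L, 30L, 50L),
    hi = c(4L, 8L, 13L, 30L, 50L, 100L),
    stringsAsFactors = FALSE)
}

checkScheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("band", "lo", "hi") %in% names(scheme)))
  if (any(scheme$lo != round(scheme$lo)) || any(scheme$hi != round(scheme$hi)))
    stop("band edges must be integers")
  if (any(scheme$lo >= scheme$hi)) stop("band edges must satisfy lo < hi")
  if (any(scheme$lo < 1) || any(scheme$hi > 100))
    stop("bands must lie inside the 1..100 Hz grid")
  scheme
}

## Number of integer bins per band (inclusive endpoints).
bandBins <- function(scheme) scheme$hi - scheme$lo + 1L

## Full-length DFT coefficients of a vector (thin wrapper kept as the single
## entry point for spectral arithmetic; the test suite holds a brute-force
## O(N^2) summation oracle against it).
.dftCoef <- function(x) stats::fft(x)

#' Welch segment length
#'
#' Length in seconds of each of \code{nSegments} equal segments covering a
#' recording of the given duration at the given fractional overlap:
#' \code{duration / ((nSegments - 1) * (1 - overlap) + 1)}. The study
#' geometry, 180 s into 8 half-overlapping segments, gives 40 s.
#'
#' @param duration recording length in seconds.
#' @param nSegments segment count.
#' @param overlap fractional overlap in [0, 1).
#' @return Segment length in seconds.
#' @examples
#' welchSegmentLength(180, 8, 0.5)   # 40
#' @export
welchSegmentLength <- function(duration, nSegments = 8L, overlap = 0.5) {
  stopifnot(duration > 0, nSegments >= 1, overlap >= 0, overlap < 1)
  duration / ((nSegments - 1) * (1 - overlap) + 1)
}

#' Welch power spectral density on the integer frequency grid
#'
#' The recording is split into \code{nSegments} equal segments at the given
#' overlap, each segment is Hamming-windowed and its squared-magnitude DFT
#' taken; per channel, the spectral estimate at each integer frequency
#' 1..100 Hz is the mean over segments at (the nearest DFT bin to) that
#' frequency. One-sided density normalization with window power correction
#' is applied; any fixed positive rescaling is immaterial downstream because
#' band powers in dB are later z-scored per feature.
#'
#' @param rec a [Recording-class]; the sampling rate must reach the 100 Hz
#'   grid (fs >= 200) and segments must be at least 1 s long.
#' @param nSegments number of segments (default 8).
#' @param overlap fractional overlap in [0, 1) (default 0.5).
#' @param window taper; only \code{"hamming"} is supported.
#' @return A [SpectrumSet-class] with the power component filled.
#' @export
welchSpectrum <- function(rec, nSegments = 8L, overlap = 0.5,
                          window = "hamming") {
  window <- match.arg(window, "hamming")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  fs <- rec@fs
  n <- ncol(rec@data)
  ls <- floor(n / ((nSegments - 1) * (1 - overlap) + 1))
  if (ls < fs) stop("recording too short: segments must be at least 1 s")
  step <- max(1L, floor(ls * (1 - overlap)))
  if ((nSegments - 1) * step + ls > n)
    stop("recording too short for ", nSegments, " segments")
  bins <- round(1:100 * ls / fs) + 1L
  if (max(bins) > floor(ls / 2) + 1L)
    stop("sampling rate too low for the 1..100 Hz grid (need fs >= 200)")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(ls - 1)) / (ls - 1))
  u <- sum(w^2)
  starts <- (0:(nSegments - 1)) * step
  nch <- nrow(rec@data)
  power <- matrix(0, nch, 100L,
                  dimnames = list(rownames(rec@data), paste0("f", 1:100)))
  for (ch in seq_len(nch)) {
    segs <- vapply(starts,
                   function(s) rec@data[ch, (s + 1):(s + ls)] * w,
                   numeric(ls))
    spec <- Mod(stats::mvfft(segs))^2            # ls x nSegments
    dens <- 2 * spec / (fs * u)                  # one-sided density
    if (ls %% 2 == 0) dens[ls / 2 + 1, ] <- dens[ls / 2 + 1, ] / 2
    power[ch, ] <- rowMeans(dens[bins, , drop = FALSE])
  }
  new("SpectrumSet", power = power, phase = matrix(0, 0, 0))
}

#' Full-record DFT phase angles on the integer frequency grid
#'
#' One DFT of the whole recording per channel; the phase at integer
#' frequency f is the argument of the coefficient at bin f * T (T the
#' duration in seconds), mapped to (-pi, pi]. The duration must be an
#' integer number of seconds so that integer frequencies are exact DFT bins
#' -- non-integer durations are rejected rather than interpolated, because
#' off-bin phases are not the quantity the preferred phase angle is defined
#' on.
#'
#' @param rec a [Recording-class] with integer-second duration and
#'   fs >= 200.
#' @return A [SpectrumSet-class] with the phase component filled.
#' @examples
#' t <- seq(0, 2, length.out = 2 * 250 + 1)[-1]
#' r <- newRecording(matrix(cos(2 * pi * 10 * t), 1), fs = 250)
#' spectrumPhase(fftPhases(r))[1, 10]   # ~0: cosine phase convention
#' @export
fftPhases <- function(rec) {
  n <- ncol(rec@data)
  tdur <- n / rec@fs
  if (abs(tdur - round(tdur)) > 1e-9)
    stop("duration must be an integer number of seconds (got ",
         format(tdur), " s)")
  tdur <- round(tdur)
  bins <- 1:100 * tdur + 1L
  if (max(bins) > floor(n / 2) + 1L)
    stop("sampling rate too low for the 1..100 Hz grid (need fs >= 200)")
  coef <- stats::mvfft(t(rec@data))              # n x channels
  phase <- t(wrapAngle(Arg(coef[bins, , drop = FALSE])))
  dimnames(phase) <- list(rownames(rec@data), paste0("f", 1:100))
  new("SpectrumSet", power = matrix(0, 0, 0), phase = phase)
}

#' Power and phase spectra together
#'
#' @inheritParams welchSpectrum
#' @return A [SpectrumSet-class] with both components.
#' @export
computeSpectra <- function(rec, nSegments = 8L, overlap = 0.5) {
  new("SpectrumSet",
      power = spectrumPower(welchSpectrum(rec, nSegments, overlap)),
      phase = spectrumPhase(fftPhases(rec)))
}

#' @describeIn SpectrumSet-class the channels x 100 power matrix.
#' @param x a [SpectrumSet-class]
#' @export
setMethod("spectrumPower", "SpectrumSet", function(x) x@power)

#' @describeIn SpectrumSet-class the channels x 100 phase matrix.
#' @export
setMethod("spectrumPhase", "SpectrumSet", function(x) x@phase)

setMethod("show", "SpectrumSet", function(object) {
  nch <- max(nrow(object@power), nrow(object@phase))
  cat("SpectrumSet:", nch, "channels on the 1..100 Hz grid;",
      if (ncol(object@power)) "power" else NULL,
      if (ncol(object@phase)) "phase" else NULL, "\n")
})

#' Band-averaged power in decibels
#'
#' For each channel and band, 10 log10 of the arithmetic mean of the
#' spectral density over the band's inclusive integer bins.
#'
#' @param spec a [SpectrumSet-class] with power.
#' @param scheme band scheme (default [bandScheme()]).
#' @return Numeric matrix channels x bands, in dB.
#' @examples
#' s <- new("SpectrumSet", power = matrix(1, 1, 100), phase = matrix(0, 0, 0))
#' bandPsdFeatures(s)   # all 0 dB on a unit flat spectrum
#' @export
bandPsdFeatures <- function(spec, scheme = bandScheme()) {
  checkScheme(scheme)
  p <- spectrumPower(spec)
  if (!ncol(p)) stop("SpectrumSet has no power component")
  out <- vapply(seq_len(nrow(scheme)), function(b) {
    10 * log10(rowMeans(p[, scheme$lo[b]:scheme$hi[b], drop = FALSE]))
  }, numeric(nrow(p)))
  out <- matrix(out, nrow = nrow(p),
                dimnames = list(rownames(p), scheme$band))
  out
}

#' Preferred phase angle and phase consistency of a set of phases
#'
#' The preferred phase angle (PPA) is the argument of the mean of the unit
#' phasors exp(i * theta) over the given phases -- magnitudes are ignored by
#' construction. Phase consistency is the modulus of that mean vector: 1
#' when all phasors coincide, near 0 when they are dispersed around the
#' circle. When the resultant all but vanishes (consistency < 1e-12) the
#' angle is undefined; it is reported as 0 with \code{degenerate = TRUE}
#' rather than raising, since downstream z-scoring tolerates it.
#'
#' @param phases numeric vector of phase angles in radians (a band's bins).
#' @return List with \code{ppa} (radians in (-pi, pi]), \code{consistency}
#'   in [0, 1], and logical \code{degenerate}.
#' @examples
#' preferredPhaseAngle(c(pi / 3, -pi / 3))   # ppa 0, consistency 0.5
#' @export
preferredPhaseAngle <- function(phases) {
  if (!length(phases) || anyNA(phases)) stop("phases must be non-empty finite")
  z <- mean(exp(1i * phases))
  r <- Mod(z)
  if (r < 1e-12) list(ppa = 0, consistency = r, degenerate = TRUE)
  else list(ppa = wrapAngle(Arg(z)), consistency = r, degenerate = FALSE)
}

#' Band-wise preferred phase angles for every channel
#'
#' @param spec a [SpectrumSet-class] with phase.
#' @param scheme band scheme (default [bandScheme()]).
#' @return List of channels x bands matrices: \code{ppa} (radians),
#'   \code{consistency} in [0, 1], logical \code{degenerate}.
#' @export
bandPpaFeatures <- function(spec, scheme = bandScheme()) {
  checkScheme(scheme)
  ph <- spectrumPhase(spec)
  if (!ncol(ph)) stop("SpectrumSet has no phase component")
  nch <- nrow(ph)
  nb <- nrow(scheme)
  dn <- list(rownames(ph), scheme$band)
  ppa <- cons <- matrix(0, nch, nb, dimnames = dn)
  degen <- matrix(FALSE, nch, nb, dimnames = dn)
  for (b in seq_len(nb)) {
    z <- rowMeans(exp(1i * ph[, scheme$lo[b]:scheme$hi[b], drop = FALSE]))
    r <- Mod(z)
    bad <- r < 1e-12
    ppa[, b] <- ifelse(bad, 0, wrapAngle(Arg(z)))
    cons[, b] <- r
    degen[, b] <- bad
  }
  list(ppa = ppa, consistency = cons, degenerate = degen)
}

#' Extract a subject x feature matrix from a cohort
#'
#' Runs the per-recording spectral pipeline (hemisphere restriction, Welch
#' power or full-record DFT phase, band reduction) and stacks one feature
#' row per subject. Feature columns are ordered channel-major, band-minor
#' and carry descriptors (channel, band, kind). For the whole-head default
#' montage and scheme this yields 151 x 6 = 906 features per kind; one
#' hemisphere yields 70 x 6 = 420.
#'
#' @param cohort list of [Recording-class] objects sharing fs, duration and
#'   channel set (the list returned by [generateCohort()] is also accepted).
#' @param kind \code{"PSD"} (Welch band power, dB) or \code{"PPA"}
#'   (preferred phase angle, radians).
#' @param scheme band scheme.
#' @param layout [SensorLayout-class]; required when \code{subset} is not
#'   \code{"all"}.
#' @param subset \code{"all"}, \code{"left"} or \code{"right"}.
#' @param nSegments,overlap Welch parameters (PSD only).
#' @return A [FeatureSet-class] (features x subjects).
#' @export
extractFeatureMatrix <- function(cohort, kind = c("PSD", "PPA"),
                                 scheme = bandScheme(), layout = NULL,
                                 subset = c("all", "left", "right"),
                                 nSegments = 8L, overlap = 0.5) {
  kind <- match.arg(kind)
  subset <- match.arg(subset)
  if (!is.null(cohort$recordings)) cohort <- cohort$recordings
  stopifnot(length(cohort) >= 1L)
  checkScheme(scheme)
  fs0 <- samplingRate(cohort[[1]])
  n0 <- ncol(recordingData(cohort[[1]]))
  ch0 <- channelNames(cohort[[1]])
  for (r in cohort) {
    if (samplingRate(r) != fs0 || ncol(recordingData(r)) != n0 ||
        !identical(channelNames(r), ch0))
      stop("cohort geometry is heterogeneous (fs, duration or channels)")
  }
  if (subset != "all" && is.null(layout))
    stop("a layout is required for hemispheric subsets")
  rows <- lapply(cohort, function(r) {
    if (subset != "all") r <- selectChannels(r, layout, subset)
    m <- if (kind == "PSD")
      bandPsdFeatures(welchSpectrum(r, nSegments, overlap), scheme)
    else
      bandPpaFeatures(fftPhases(r), scheme)$ppa
    as.vector(t(m))   # channel-major, band-minor
  })
  vals <- do.call(cbind, rows)   # features x subjects
  chn <- if (subset == "all") ch0
         else ch0[hemisphereOf(layout)[ch0] == subset]
  desc <- DataFrame(
    channel = rep(chn, each = nrow(scheme)),
    band = rep(scheme$band, times = length(chn)),
    kind = kind)
  rownames(vals) <- paste(desc$channel, desc$band, kind, sep = ".")
  colnames(vals) <- vapply(cohort, subjectId, character(1))
  se <- SummarizedExperiment(
    assays = list(features = vals), rowData = desc,
    colData = DataFrame(subject = colnames(vals),
                        label = vapply(cohort, recordingLabel, character(1)),
                        row.names = colnames(vals)),
    metadata = list(kindTag = kind))
  new("FeatureSet", se)
}
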