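## Synthetic two-class oscillatory cohorts. Each affected channel carries,
## per band, unit sinusoids at every integer band frequency whose phases
## are drawn from a von Mises distribution -- so the injected preferred
## angle mu and concentration kappa translate directly into the measured
## preferred phase angle and phase consistency -- on top of white Gaussian
## noise. Class differences live either in the band amplitudes (power
## effects), the phase parameters (phase effects), or both.

#' Construct a class-conditional effect specification
#'
#' @param scheme band scheme (default [bandScheme()]).
#' @param amplitude sinusoid amplitude per band: a single value recycled, or
#'   a vector/named vector over bands (unnamed bands default to 0).
#' @param mu preferred phase angle per band (radians), same conventions.
#' @param kappa von Mises concentration per band (>= 0; 0 = uniform
#'   phases), same conventions.
#' @param noiseSd white-noise standard deviation (signal units).
#' @param affectedChannels integer channel indices carrying the
#'   oscillations; all other channels are pure noise.
#' @return An [EffectSpec-class].
#' @examples
#' effectSpec(amplitude = c(theta = 1), mu = c(theta = pi / 2),
#'            kappa = c(theta = 5), affectedChannels = 1:5)
#' @export
effectSpec <- function(scheme = bandScheme(), amplitude = 0, mu = 0,
                       kappa = 0, noiseSd = 1,
                       affectedChannels = integer()) {
  checkScheme(scheme)
  expand <- function(v) {
    out <- stats::setNames(rep(0, nrow(scheme)), scheme$band)
    if (is.null(names(v))) {
      out[] <- rep(v, length.out = nrow(scheme))
    } else {
      bad <- setdiff(names(v), scheme$band)
      if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "))
      out[names(v)] <- v
    }
    out
  }
  new("EffectSpec", scheme = scheme, amplitude = expand(amplitude),
      mu = expand(mu), kappa = expand(kappa), noiseSd = noiseSd,
      affectedChannels = as.integer(affectedChannels))
}

setMethod("show", "EffectSpec", function(object) {
  act <- which(object@amplitude > 0)
  cat("EffectSpec: noise sd", object@noiseSd, ";",
      length(object@affectedChannels), "affected channels;",
      if (length(act)) paste0(names(object@amplitude)[act], "(a=",
                              object@amplitude[act], ", mu=",
                              round(object@mu[act], 3), ", kappa=",
                              object@kappa[act], ")", collapse = " ")
      else "no oscillations", "\n")
})

#' von Mises random angles
#'
#' Best & Fisher (1979) wrapped-Cauchy rejection sampler; kappa = 0 gives
#' uniform angles on (-pi, pi].
#'
#' @param n sample count.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrapAngle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  wrapAngle(out + mu)
}

#' Generate one synthetic recording
#'
#' Per affected channel the signal is the sum over bands b and integer band
#' frequencies f of \code{amplitude[b] * cos(2 pi f t + phi)}, with phi
#' drawn independently per (channel, frequency) from
#' von Mises(mu[b], kappa[b]), plus white Gaussian noise everywhere.
#' Unaffected channels are pure noise. The duration must be an integer
#' number of seconds so every integer frequency is an exact DFT bin of the
#' full record.
#'
#' @param spec an [EffectSpec-class].
#' @param label class label for the recording.
#' @param duration seconds (integer).
#' @param fs sampling rate in Hz (>= 200 for the 1..100 Hz grid).
#' @param nChannels channel count; channel names are taken from
#'   \code{layout} when given.
#' @param seed integer seed; identical seeds give identical recordings.
#' @param subjectId subject identifier.
#' @param layout optional [SensorLayout-class] supplying channel names.
#' @return List with the [Recording-class] (\code{recording}) and the drawn
#'   phase matrix (\code{phases}, channels x 100, NA where no sinusoid).
#' @export
generateRecording <- function(spec, label = "unknown", duration = 30,
                              fs = 250, nChannels = 20L, seed = 1L,
                              subjectId = "synth", layout = NULL) {
  if (abs(duration - round(duration)) > 1e-9)
    stop("duration must be an integer number of seconds")
  if (!is.null(layout)) nChannels <- length(layout@channelNames)
  if (length(spec@affectedChannels) &&
      max(spec@affectedChannels) > nChannels)
    stop("affectedChannels outside the montage")
  n <- round(duration * fs)
  tt <- (0:(n - 1)) / fs
  withLocalSeed(seed, {
    data <- matrix(stats::rnorm(nChannels * n, sd = spec@noiseSd),
                   nChannels, n)
    phases <- matrix(NA_real_, nChannels, 100L)
    active <- which(spec@amplitude > 0)
    for (ch in spec@affectedChannels) {
      for (b in active) {
        fr <- spec@scheme$lo[b]:spec@scheme$hi[b]
        phi <- rvonmises(length(fr), spec@mu[b], spec@kappa[b])
        phases[ch, fr] <- phi
        ## sum of band sinusoids: |fr| x n phase-offset cosines
        data[ch, ] <- data[ch, ] + spec@amplitude[b] *
          colSums(cos(2 * pi * outer(fr, tt) + phi))
      }
    }
    chn <- if (is.null(layout)) sprintf("ch%03d", seq_len(nChannels))
           else layout@channelNames
    rownames(data) <- chn
    list(recording = newRecording(data, fs = fs, subjectId = subjectId,
                                  label = label),
         phases = phases)
  })
}

#' Generate a labeled two-class cohort
#'
#' @param nPerClass subjects per class (default 30).
#' @param specTD,specASD [EffectSpec-class] per class (same geometry).
#' @param layout montage (default [deskMontage()], 20 channels).
#' @param duration,fs recording geometry (default 30 s at 250 Hz, a
#'   desk-scale stand-in for the full 151-channel, 180 s, 1000 Hz study
#'   geometry).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return List: \code{recordings} (2 * nPerClass [Recording-class]s, TD
#'   first), \code{truth} (the two specs plus per-subject drawn phases),
#'   \code{seed}.
#' @export
generateCohort <- function(nPerClass = 30L, specTD, specASD,
                           layout = deskMontage(), duration = 30,
                           fs = 250, seed = 1L) {
  stopifnot(is(specTD, "EffectSpec"), is(specASD, "EffectSpec"))
  if (!identical(specTD@scheme, specASD@scheme))
    stop("the two specs must share a band scheme")
  recs <- vector("list", 2L * nPerClass)
  phases <- vector("list", 2L * nPerClass)
  i <- 0L
  for (cl in c("TD", "ASD")) {
    spec <- if (cl == "TD") specTD else specASD
    for (s in seq_len(nPerClass)) {
      i <- i + 1L
      g <- generateRecording(spec, label = cl, duration = duration,
                             fs = fs, seed = deriveSeed(seed, i),
                             subjectId = sprintf("%s%02d", cl, s),
                             layout = layout)
      recs[[i]] <- g$recording
      phases[[i]] <- g$phases
    }
  }
  list(recordings = recs,
       truth = list(specTD = specTD, specASD = specASD, phases = phases),
       seed = as.integer(seed))
}

#' The injected preferred phase angle of a class and band
#'
#' The asymptotic preferred phase angle of affected channels is the von
#' Mises mean direction mu; defined only for kappa > 0.
#'
#' @param spec an [EffectSpec-class].
#' @param band band name.
#' @return mu in radians.
#' @export
truePpa <- function(spec, band) {
  if (!(band %in% spec@scheme$band)) stop("unknown band: ", band)
  if (spec@kappa[band] == 0)
    stop("kappa = 0: no defined preferred angle for band ", band)
  unname(spec@mu[band])
}

#' Preset cohort effect specifications
#'
#' Fixed desk-scale study conditions for the end-to-end checks:
#' \describe{
#'   \item{phase-only}{equal theta amplitudes in both classes; the classes
#'     differ only in the theta preferred angle (0 vs pi/2 at kappa = 5) on
#'     channels 1..5.}
#'   \item{power-only}{uniform phases (kappa = 0); the classes differ only
#'     in theta amplitude (1 vs 1.4) on channels 1..5.}
#'   \item{both}{the phase-only theta effect plus an alpha-amplitude effect
#'     (1 vs 1.4) on channels 1..10 -- two effects carried by disjoint
#'     bands, so the phase and power feature sets see independent signals.}
#'   \item{null}{identical specs in both classes (no class signal).}
#' }
#' Noise sd is 1 throughout.
#'
#' @param preset one of \code{"phase-only"}, \code{"power-only"},
#'   \code{"both"}, \code{"null"}.
#' @return List with elements \code{specTD} and \code{specASD}.
#' @export
cohortPreset <- function(preset = c("phase-only", "power-only", "both",
                                    "null")) {
  preset <- match.arg(preset)
  base <- function(...) effectSpec(..., noiseSd = 1)
  switch(preset,
    "phase-only" = list(
      specTD = base(amplitude = c(theta = 1), mu = c(theta = 0),
                    kappa = c(theta = 5), affectedChannels = 1:5),
      specASD = base(amplitude = c(theta = 1), mu = c(theta = pi / 2),
                     kappa = c(theta = 5), affectedChannels = 1:5)),
    "power-only" = list(
      specTD = base(amplitude = c(theta = 1), kappa = c(theta = 0),
                    affectedChannels = 1:5),
      specASD = base(amplitude = c(theta = 1.4), kappa = c(theta = 0),
                     affectedChannels = 1:5)),
    "both" = list(
      specTD = base(amplitude = c(theta = 1, alpha = 1),
                    mu = c(theta = 0), kappa = c(theta = 5),
                    affectedChannels = 1:10),
      specASD = base(amplitude = c(theta = 1, alpha = 1.4),
                     mu = c(theta = pi / 2), kappa = c(theta = 5),
                     affectedChannels = 1:10)),
    "null" = list(
      specTD = base(amplitude = c(theta = 1), mu = c(theta = 0),
                    kappa = c(theta = 5), affectedChannels = 1:5),
      specASD = base(amplitude = c(theta = 1), mu = c(theta = 0),
                     kappa = c(theta = 5), affectedChannels = 1:5)))
}

#' Cohort generator for a preset
#'
#' Convenience wrapper used by the repeated-experiment checks: returns a
#' \code{function(seed)} drawing a fresh preset cohort.
#'
#' @param preset preset name (see [cohortPreset()]).
#' @param nPerClass subjects per class.
#' @param layout,duration,fs cohort geometry.
#' @return A function of one argument (the seed).
#' @export
presetCohortFun <- function(preset, nPerClass = 30L, layout = deskMontage(),
                            duration = 30, fs = 250) {
  specs <- cohortPreset(preset)
  function(seed) generateCohort(nPerClass, specs$specTD, specs$specASD,
                                layout, duration, fs, seed)
}
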