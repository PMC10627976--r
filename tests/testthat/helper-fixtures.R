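# Programmatic fixtures shared across the suite. All geometries are chosen
# so that integer frequencies fall on exact DFT bins: fs = 250 with 9 s
# gives Welch segments of 500 samples (2 s, bins at 2f) and full-record
# bins at 9f; fs = 200 with 36 s gives 8 s segments (bins at 8f).

# One-channel recording holding an arbitrary signal.
toneRecording <- function(x, fs, subjectId = "tone", label = "unknown") {
  newRecording(matrix(x, nrow = 1), fs = fs, subjectId = subjectId,
               label = label)
}

# Time axis starting at 0 (so cosine phases are exact).
timeAxis <- function(duration, fs) (0:(duration * fs - 1)) / fs

# Small fast cohort for pipeline tests: 9 s at 250 Hz.
smallCohort <- function(preset = "both", nPerClass = 10L, seed = 1L) {
  specs <- cohortPreset(preset)
  generateCohort(nPerClass, specs$specTD, specs$specASD,
                 layout = deskMontage(), duration = 9, fs = 250,
                 seed = seed)
}

smallConfig <- function(seed = 1L, ...) {
  experimentConfig(seed = seed, ...)
}

# Direct FeatureSet from a subjects x features matrix (bypassing spectra),
# for selection / fusion unit tests.
makeFeatureSet <- function(values, labels, kind = "PSD",
                           subjects = sprintf("S%03d", seq_len(nrow(values)))) {
  nf <- ncol(values)
  vals <- t(values)
  rownames(vals) <- sprintf("ch%03d.delta.%s", seq_len(nf), kind)
  colnames(vals) <- subjects
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals),
    rowData = S4Vectors::DataFrame(
      channel = sprintf("ch%03d", seq_len(nf)),
      band = rep("delta", nf), kind = kind),
    colData = S4Vectors::DataFrame(subject = subjects, label = labels,
                                   row.names = subjects),
    metadata = list(kindTag = kind))
  new("FeatureSet", se)
}

# Brute-force O(N^2) DFT, the oracle for fft-based spectra.
bruteDft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

# Circular mean of angles.
circMean <- function(theta) Arg(mean(exp(1i * theta)))

# Separable two-blob toy for classifier tests (d-prime ~ 6).
separableToy <- function(n = 40L, seed = 1L, dprime = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
             matrix(rnorm(n, dprime, 1), n / 2, 2))
  y <- rep(c("TD", "ASD"), each = n / 2)
  idx <- sample(n)
  list(X = X[idx, ], y = y[idx])
}
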