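---
title: "Spectral power and preferred-phase-angle fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral power and preferred-phase-angle fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the feature
definitions and their assumptions, the classifier and cross-validation
contracts, the fusion rules, what the synthetic cohort generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## Features

### Band power (PSD)

Per channel, the spectral density is the Welch estimate: the recording is
split into `nSegments = 8` equal segments with 50% overlap (a T-second
recording gives segments of `T / ((nSegments − 1)/2 + 1)` seconds; 180 s
gives 40 s), each segment is Hamming-windowed, and the squared-magnitude
DFT is averaged over segments. The per-band feature is the decibel value
of the arithmetic band mean,

PSD_fb = 10 log10( (1/N_fb) Σ_{f = fb_min}^{fb_max} S(f) ),

on the integer 1–100 Hz grid. Band edges are **inclusive on both sides**
(alpha = {8,…,13}, N_fb = 6): that is the only reading consistent with
the bin-count arithmetic the band scheme is defined by, and it means
boundary bins (4, 8, 13, 30, 50 Hz) contribute to two adjacent bands.

Welch scaling is one-sided density normalization with window power
correction. Any fixed positive rescaling would do equally well: the dB
features are z-scored per feature downstream, which removes affine
offsets. We state the convention only so the spectra are interpretable on
their own.

Two numerical points. First, the segment-length formula gives non-integer
sample counts for some geometries (e.g. the desk-scale 30 s default at
250 Hz); segment length and step are floored, and each integer frequency
maps to its nearest DFT bin. For the full study geometry (180 s, 8
segments) and for the geometries used in the test suite the bins are
exact. Second, the sampling rate must reach the grid (fs ≥ 200), or the
100 Hz bin would not exist; this is checked, not assumed.

### Preferred phase angle (PPA)

Phases come from **one full-length DFT of the whole recording**, not from
Welch segments: θ(f) is the argument of the coefficient at bin f·T,
which is exact when the duration T is an integer number of seconds.
Non-integer durations are rejected rather than interpolated — an off-bin
phase is not the quantity the feature is defined on. Per channel and
band,

PPA_fb = ∠( (1/N_fb) Σ_f exp(i θ(f)) ),

the circular mean direction of **unit** phasors: spectral magnitudes are
deliberately ignored, so the phases of low-power bins count exactly as
much as high-power ones. The modulus of the same mean vector is the phase
consistency in [0, 1]. When the resultant all but vanishes
(consistency < 1e−12) the angle is undefined; it is reported as 0 with a
degeneracy flag rather than as an error, because downstream z-scoring
tolerates the value and a hard failure would be disproportionate.

Zero-phase (forward–backward) filtering is mandated for the band-pass and
notch preprocessing precisely because PPA is phase-based: a causal filter
group delay would rotate every θ(f) by a frequency-dependent amount.

PPA values are treated as linear reals in (−π, π] by the normalization
and t-test stages. This is a known simplification: a class difference
that straddles the ±π wrap can be attenuated or missed by a linear
t-test. Circular-statistics alternatives are out of scope. Relatedly,
z-scoring does *not* confine PPA features to ±1 rad — it confines them to
unit sample variance, whatever the angular spread was; we implement plain
z-scoring and note the distinction.

## Selection and classification

**Normalization.** Per-feature z-scoring with mean and sample SD fitted
on the **training subjects of the current fold only**, then applied to
all subjects. Constant features get SD := 1 and a flag. Fitting on
training rows only is the leakage-free scope; whether validation rows may
also inform normalization is a defensible alternative we did not take.

**Ranking.** Classical pooled-variance two-sample t-test per feature
(Welch's variant is available by argument), two-sided p-values, computed
over training rows only. Features with p below a threshold are kept,
ranked by ascending p with ties broken by column index for determinism.
The threshold is swept over 0.005–0.05 in steps of 0.005 and chosen by
mean validation accuracy (ties to the smaller threshold). Thresholds here
are tuning knobs, not inference; no multiple-testing correction is
applied, by design.

**Classifier.** A two-layer feedforward network: tanh hidden layer of 10
units, two softmax outputs read as posterior-like scores P(TD), P(ASD)
summing to 1. Loss is mean squared error against one-hot targets with a
goal of 1e−5, at most 10000 full-batch epochs. Early stopping monitors
the validation MSE after every epoch and stops after 6 consecutive
increases since the minimum; the minimum-validation-error weights are
returned regardless of where training stopped. The optimizer is
full-batch resilient backpropagation (iRPROP−) — deterministic given the
seeded uniform initializer, robust to feature-count changes across
thresholds, and without line searches; the model class and the
early-stopping contract, not the optimizer identity, are what the results
depend on. Hard labels use ASD ⇔ P(ASD) ≥ 0.5; the tie at exactly 0.5 is
assigned to ASD so that the two half-open decision rules compose into one
total rule.

**Cross-validation.** Stratified subject-exclusive fivefold: the five
test sets partition the cohort; within each fold the remaining subjects
split 3:1 per class into training and validation (60 balanced subjects
give 36/12/12). Fold assignment is seeded stratified randomization — the
per-class set sizes imply stratification even though nothing else about
the assignment is pinned down. One p-threshold is chosen per feature kind
across folds (mean validation accuracy), mirroring reports that quote a
single operating threshold per feature type.

A threshold that selects no feature in some fold is handled, not fatal:
that fold's model is the uninformed 0.5/0.5 posterior, which is
chance-level by the tie rule, so over-strict thresholds simply lose the
validation sweep. This matters on null cohorts, where the strictest
thresholds select nothing with substantial probability.

## Fusion

Feature-level fusion concatenates the two normalized feature matrices
(PSD columns first) and re-runs selection on the fused matrix — the
selection stage is the dimensionality control. Score-level fusion forms
`w·P_psd + (1−w)·P_ppa` per subject with `w` swept over {0.1,…,0.9};
the (threshold, weight) pair is chosen jointly on validation accuracy,
reusing the already-trained single-kind models, with ties to the smaller
threshold and then the earlier weight. Product/max/min fusion rules and
weight-optimization algorithms are deliberately absent.

The complementarity criterion is the Pearson correlation between the two
models' per-subject training ASD scores. "One coefficient per what?" was
genuinely ambiguous; we define one coefficient per cross-validation
repetition (reseeded runs, training scores pooled within a run), which
yields a histogram across repetitions without inventing per-feature score
semantics. Repetitions with a constant score vector are skipped and
counted. Note that on strongly separable cohorts both models' training
scores approach the class indicator and the correlation approaches 1
regardless of how complementary the *features* are; the criterion is
informative in the noisy regime it was designed for.

## The synthetic cohort generator

Each affected channel carries, per band, unit sinusoids at every integer
band frequency with amplitude a_{class,band}; the sinusoid phases are
drawn independently per (subject, channel, frequency) from a von Mises
distribution with preferred angle μ and concentration κ, on top of white
Gaussian noise of SD σ everywhere. The von Mises family was chosen
because it is the canonical unimodal circular distribution and κ maps
monotonically to phase consistency, giving analytic expectations for the
recovery tests (circular mean of measured PPA → μ; spread shrinking in
κ; class band-power difference → 20·log10(a_ASD/a_TD) at high SNR). The
sampler is the Best–Fisher (1979) rejection algorithm, written
in-package.

The default geometry is desk-scale — 20 channels (9/2/9
left/midline/right), 30 s at 250 Hz, 30 subjects per class — a stand-in
for the full 151-channel (70/11/70), 180 s, 1000 Hz study geometry,
which the generator can also produce when asked. Presets fix the study
conditions for the end-to-end checks: *phase-only* (equal theta
amplitudes, μ 0 vs π/2 at κ = 5, channels 1–5), *power-only* (uniform
phases, theta amplitude 1 vs 1.4), *both* (the two effects in disjoint
bands), *null* (identical specs); noise SD 1 throughout. κ = 5 and the
1.4 amplitude ratio were chosen once as clearly detectable but not
absurd effects at these sample sizes; with fixed per-class amplitudes the
only within-class variability is phase- and noise-driven, so both
single-kind classifiers can saturate near 100% on their own effect —
useful for checking the *ordering* of models, not for reproducing any
clinical accuracy level.

What the generator does **not** emulate: 1/f background spectra, between-
subject amplitude variability, sensor covariance and field spread,
artifacts, or any forward model. Passing tests therefore demonstrate the
pipeline's correctness and calibration — chance-level behavior on null
cohorts, recovery of injected parameters, the expected model ordering
under phase-only/power-only/both effects — and nothing about clinical
effect sizes on real MEG.

## Problem sizes used by the checks

The stochastic end-to-end checks run the full pipeline (10-threshold
sweep × 5 folds × 3 feature kinds per run) on the desk-scale geometry:
20 reseeded repetitions for the null calibration, and 12 reseeded
repetitions per effect preset for the dominance comparisons; parameter
recovery uses 30 + 30 subjects. The acceptance script uses 5 repetitions
per preset. These sizes were fixed once for single-CPU practicality; the
directions and tolerances of the assertions do not depend on them.

## Known limitations

- Linear treatment of circular PPA values (wrap-around effects).
- Nearest-bin mapping for non-exact Welch geometries (exact for the study
  geometry).
- The 50 Hz notch leaves a depressed bin inside both gamma bands; the bin
  is retained, since no exclusion rule is defined for it.
- The notch is applied once to the continuous recording, not re-applied
  after segmentation.
- Upstream artifact handling (ICA, bad-sensor interpolation) is out of
  scope; recordings are assumed cleaned.
- With the fixed-amplitude generator, PSD separability is nearly
  noise-free at any amplitude contrast; dominance checks are about
  ordering, not graded effect sizes.
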