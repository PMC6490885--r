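---
title: "Hierarchical frequency tagging and multispectral phase coherence: methods"
author: "hftmspc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical frequency tagging and multispectral phase coherence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftmspc)
```

## The problem

Hierarchical frequency tagging (HFT) drives a visual stimulus with two
simultaneous periodicities. A slow cyclic wavelet scramble (SWIFT) makes an
image recognisable exactly once per cycle at `f1` (around 1 Hz), tagging
object-recognition activity high in the visual hierarchy. A fast sinusoidal
contrast modulation at `f2` (12 or 15 Hz) evokes a steady-state visual
response (SSVEP) from early visual cortex. When the two tagged signals
interact nonlinearly anywhere in the system, spectral energy appears at
intermodulation (IM) frequencies `n1*f1 + n2*f2` with non-zero integer
weights; the two second-order components `f2 - f1` and `f2 + f1` are the
primary analysis targets.

The package's core statistic is the multispectral phase coherence (MSPC):
for an IM component with weights `n_r` on input frequencies `f_r`, each
analysis epoch `k` contributes a phase residual
`sum_r n_r * phi_I,k(f_r) - phi_O,k(f_sum)`, and the MSPC is the resultant
length of these residuals across epochs — 1 when the IM phase is a
deterministic function of the input phases, near `sqrt(pi)/(2*sqrt(K))` for
`K` independent epochs when it is not.

The scientifically load-bearing idea is *where the input phases come from*:

* **Stimulus-referenced** (`mspc_stim`): the input phases are those of the
  on-screen modulations — the contrast cosine and the SWIFT cycle phase.
* **Response-referenced** (`mspc_res`): the input phases are the same
  channel's EEG phases at `f1` and `f2`, epoch by epoch.

Constant processing delays add constant phase offsets and leave both
variants identical — this is provable from the formula and is tested
literally (`tau_jitter_sd = 0` implies `|stim - res| < 1e-6`). The two
variants dissociate only when the latency between stimulus and response
*varies* across epochs: an interaction locked to the stimulus keeps
stimulus-referenced coherence and loses response-referenced coherence, and
an interaction happening at the (jittered) response level does the
opposite. That dissociation is the package's central, ground-truth-testable
claim.

## SWIFT stimulus synthesis

`swift_scramble()` decomposes an image with a 6-level orthogonal 2-D
wavelet transform and represents the local contour at each location and
scale as the 3-vector of detail coefficients (horizontal, vertical,
diagonal). For each such vector it draws two random vectors of identical
norm and rotates the original along the circle through the three points.
All three points lie on the sphere of the vector's norm, so the whole path
does too: local energy (hence luminance, contrast and spatial-frequency
content) is conserved at every frame to machine precision, while the joint
orientation structure — the contours — is destroyed smoothly and
cyclically. The frame at rotation angle zero is the original image; the
frame at angle pi is the most scrambled and seeds the matched noise
sequence (`make_noise_sequence()`), which shares the image's low-level
statistics but never resolves into it.

Two implementation choices matter:

* **Wavelet family.** The transform must be orthogonal to numerical
  precision, otherwise rotated coefficients do not invert exactly and the
  conservation laws fail. Finite FIR approximations of band-limited
  (Meyer-type) wavelets are only approximately orthogonal (round-trip
  errors around 1e-2 at these image sizes), so the package uses the
  least-asymmetric Daubechies sym8 filter: smooth, near-symmetric and
  exactly orthogonal, giving round-trip errors near 1e-12. The scrambling
  algorithm is agnostic to this choice.
* **Degenerate coefficients.** Zero-norm coefficient vectors have no
  meaningful rotation circle and are kept constant; near-collinear random
  draws are redrawn.

`contrast_modulate()` applies the SSVEP contrast scale
`c(t) = lo + (hi - lo) * (1 + cos(2*pi*f2*t)) / 2` about each frame's mean,
with default bounds (0.30, 1.00) — a 70% modulation depth that leaves the
image identifiable at the trough. The phase convention (maximum contrast at
`t = 0`, SWIFT phase zero at peak frames) is arbitrary but fixed: MSPC is
offset-invariant, so any constant convention is valid, and fixing one makes
every phase comparison in the package reproducible.

## Trial schedules

`build_exp1_schedule()` implements the expectation design: one face and one
house image alternate at 1.2 Hz following a repeating 5-6 image pattern,
with the category flipped at a chosen violation cycle. The same category
series serves the pattern-violation task (target = the flip) and the
image-repetition task (target = the first run of 3-4 identical images,
which the flip creates), so paired schedules are visually identical and
only the task differs. Indices are 1-based throughout, as is conventional
in R; the worked six-image pattern places the target at cycle 18.

`build_exp2_schedule()` implements the attention design: two image streams
at 0.8 and 1.0 Hz, alpha-blended, under a 12 Hz contrast modulation. Each
stream shows its image in only a `presence` fraction of cycles (the
experimental range is 0.70-0.85) and the matched noise sequence otherwise;
with the 31.5 s default duration this yields 17-26 countable images per
stream. `build_cross_schedule()` adds the central-cross control task with
inter-event jitter uniform on 850-1000 ms — deliberately aperiodic so the
cross contributes only a smeared spectral ridge near 1/0.925 Hz.

## The synthetic-EEG generator

`simulate_trial()` produces multichannel EEG whose statistical structure is
exactly what the analysis assumes, with known ground truth:

* SWIFT drive: cosine at `f1` plus 2 harmonics decaying by 0.5 per order
  (real SWIFT responses are non-sinusoidal); SSVEP drive: cosine at `f2`.
  Amplitudes default to 1 uV.
* A **stimulus-locked interaction** `g_low * s1(t - tau) * s2(t - tau)`
  with fixed latency `tau = 100` ms.
* **Response-level signals** `r1, r2`: the drives delayed by
  `tau + delta_e`, where `delta_e ~ N(0, (80 ms)^2)` is redrawn once per
  analysis-epoch-length block. The **response-level interaction** is
  `g_high * r1 * r2`. Block-constant jitter is the minimal mechanism that
  dissociates the two MSPC variants, because phases are extracted once per
  epoch; continuous drift would only blur it.
* The measured fundamentals are emitted from the response level, so the
  response-referenced variant sees the jittered phases — for a
  response-level interaction the jitter cancels inside the residual and
  coherence survives; for a stimulus-locked interaction it does not.
* Independent `1/f` noise per channel (exponent 1). No spatial correlation
  is modelled: scalp realism is a non-goal, and the group analyses treat
  channels through explicit random effects instead.

The jitter magnitude (80 ms SD) is a free parameter of the generator: the
empirical literature does not quantify per-epoch latency variability at
this granularity, and the chosen value makes the high-frequency phase
`2*pi*f2*delta` wrap several times, i.e. it represents the regime where
response timing is effectively decoupled from the stimulus clock. The
default noise RMS (1.2 uV) was calibrated once so that the fundamental
amplitude SNR in a 10-s epoch spectrum is approximately 5, the working
regime the analyses assume; both are documented here rather than tuned per
experiment.

What the generator deliberately does *not* emulate: eye blinks and EMG
morphology (artifact tests use stylised spikes, steps and drifts), volume
conduction, between-channel noise correlation, and non-stationary
amplitudes. Passing tests on this generator therefore demonstrate that the
estimator and inference chain recover the intended phase structure, not
that real EEG satisfies the generative assumptions.

## Preprocessing and exclusion rules

`standardize()` resamples to 500 Hz, high-passes at 0.3 Hz and re-references
to the channel average. The default high-pass is a zero-phase spectral
filter that zeroes components strictly below the cutoff: it is exactly
idempotent (standardizing twice is a no-op, which the test suite asserts at
1e-9) and satisfies the attenuation contract (at least 20 dB at 0.05 Hz, at
most 0.5 dB at 15 Hz). For real, non-stationary recordings a forward-
backward Butterworth is available via `method = "butter"`, and a narrow
spectral notch at 50/100 Hz behind `notch_50hz = TRUE`; the synthetic data
carry no mains component, so it is off by default.

`flag_noise()` applies three per-sample criteria per channel — absolute
amplitude above 80 uV, jump above 30 uV from the previous sample, deviation
beyond 5 SD of the whole-trial channel mean — then marks cycles with more
than 2% noisy samples as noisy and channels noisy in more than 10% of
cycles as bad. The SD criterion uses the standardized signal; the ordering
(filter before SD) is a documented choice and configurable by simply
calling `flag_noise()` on the raw recording instead. Bad channels are
replaced by the inverse-distance-weighted mean of their 4 nearest good
neighbours on an idealised spherical montage (`montage_1010()`); spherical
spline interpolation would require order and regularisation choices that
the downstream analyses are insensitive to, so the simpler deterministic
scheme is used and documented as such. `apply_exclusions()` implements the
five trial/participant rules (10% bad channels per trial, 20% bad trials,
press-before-target or no press, count error beyond +/-3, 30% invalid
responses).

## Spectral analysis

All analysis frequencies are placed on exact FFT bins — epochs are chosen
so that every tagged and IM frequency completes an integer number of cycles
(`epoch_for_mspc()` refuses configurations that do not) — and a rectangular
window is used. Tapering is deliberately avoided: with exact-bin
frequencies leakage is already zero, and a taper would smear tagged energy
into neighbours that the SNR estimator treats as noise. Full-trial spectra
follow length-dependent rules: 25-s window (3-28 s) for the dual-frequency
design (0.04 Hz bins), zero-padding to 20 s for long variable-length trials
(0.05 Hz bins), first 10 s for short ones (0.1 Hz bins). Phases from padded
spectra are not used for coherence: MSPC consumes unpadded within-trial
epochs only, so padding affects amplitude bookkeeping alone. The amplitude
SNR divides the amplitude at a frequency by the arithmetic mean of its
neighbouring bins (4 per side at 0.1 Hz bins, 8 per side at 0.04 Hz bins),
excluding bins occupied by harmonics or IMs up to order 4.

## Coherence estimation choices

Each epoch's FFT phase is referenced to the epoch's own start, and the
stimulus phase is evaluated at the same start time: with exact-bin
frequencies the FFT phase of a cosine equals its phase at the window start,
so the two references are directly comparable. Overlapping epochs (1-s
step) are used as configured; overlap induces serial dependence among
epochs, which inflates both observed values and the permutation null
equally — `null_calibrate()` shuffles the epoch pairing within the trial,
preserving each margin. The closed-form independence expectation
`sqrt(pi)/(2*sqrt(K))` is reported alongside every trial result as
`null_mean`. A single epoch is degenerate (the statistic is identically 1)
and flagged rather than dropped.

Higher-order couplings need no special-case code: `mspc_spec()` accepts any
input set and integer weights, so the fourth-order component `2f1 + 2f2`
can be referenced either to the second harmonics with weights (1, 1) or to
the fundamentals with weights (2, 2).

## Group inference

`roi_aggregate()` averages the two second-order IM values over a fixed
posterior region of 17 electrodes (3 occipital, 5 parieto-occipital, 9
parietal; the ROI is data, not code). Condition contrasts are
likelihood-ratio tests between maximum-likelihood mixed models
(`lrt_contrast()`, built on lme4), with the degrees of freedom equal to the
dropped fixed-effect parameters. `study_contrasts()` includes a random
intercept per trial in addition to the participant intercept: channels
within a trial share that trial's latency-jitter realisation, so treating
them as independent replicates would be anticonservative — omitting the
trial term roughly halves the dissociation recovery rate by producing
spurious "effects" of the should-be-null variant. The
`interaction_analysis()` helper fits the graded-expectation by binary-
attention interaction model and the two post-hoc contrasts (expectation
within attended; attention within expected after a median split), and a
participant-level sign-flip permutation contrast (`perm_contrast()`) is
provided because coherence values live on [0, 1] and mixed models can
misbehave near the bounds.

## Problem sizes and defaults used by the tests and scripts

The simulation studies use 30-s trials at 250 Hz with 4 channels, 5-s
epochs stepping by 1 s (K = 25 epochs per trial, satisfying the K >= 20
regime the dissociation property assumes), 15 participants per simulated
study, and condition gains 0.6 vs 0.3 (a twofold modulation of the
targeted interaction gain; the untargeted gain is 0). These sizes keep a
full 100-study dissociation run and the 500-table mixed-model calibration
comfortably within a few minutes on one CPU while leaving all effects far
from both floor and ceiling. Sampling at 250 Hz rather than 500 Hz changes
nothing statistically — every analysis frequency remains on an exact bin —
and halves the cost.

## Known limitations

* The generator's cascade is phase-deterministic given the jitter draws;
  real nonlinear integration may produce partially coherent mixtures that
  would land the two variants at intermediate values rather than the clean
  poles simulated here.
* The idealised montage supports distance-based interpolation but is not a
  digitised head model; do not use it for source-level geometry.
* The brick-wall high-pass is ideal for stationary tagged signals but can
  ring around large isolated transients; use the Butterworth option before
  artifact inspection of real recordings.
* Mixed-model likelihood-ratio p-values rely on the chi-squared asymptotics;
  at 15 participants the calibration tests show mild conservatism (empirical
  type-I error around 0.04 at nominal 0.05), which the sign-flip permutation
  contrast sidesteps.
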