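---
title: "Methods: tissue perfusion and single-vessel Doppler quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue perfusion and single-vessel Doppler quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopplerperf)
```

## The measurement problem

A color-Doppler cine of a focal lesion encodes, frame by frame, the
beam-projected blood velocity at every pixel where the scanner detected
flow, via a colorbar lookup table (LUT). Two quantification philosophies
coexist:

* **Tissue perfusion (DTPM)** treats the whole region of interest (ROI) as
  the measurand. It needs no angle correction and no vessel identification,
  but it averages over heterogeneous, obliquely insonated vessels, so its
  velocity scale is biased low by an unknown geometric factor.
* **Single-vessel flow (SVFM)** reproduces the classic pulsed-wave Doppler
  measurement on the largest vessel with a known flow direction. It restores
  the true velocity scale through `1/cos θ` angle correction, but the
  correction amplifies angle error without bound as θ approaches 90°, and
  vessel diameter — which enters volume flow quadratically — is hard to
  measure at ultrasound resolution.

The package implements both routes and the statistics to compare their
discriminatory power on a labeled cohort, so that the trade-off can be
studied quantitatively.

## Decoding model

A pixel is *perfused* when its chroma, `max(R,G,B) − min(R,G,B)`, exceeds a
threshold (default 24/255). This exploits the construction of Doppler
overlays: the B-mode background is gray (zero chroma), the overlay saturated.
Perfused pixels take the velocity of the nearest LUT color in Euclidean RGB
distance; distance ties resolve towards the smaller speed, so decoding never
inflates perfusion. The default synthetic colorbar uses 128 geometrically
spaced levels per sign branch over 0.05–24 cm/s, keeping the relative
quantization error near 2.5% across three decades — tissue-level mean
velocities sit an order of magnitude below single-vessel peaks, so a linear
bar fine enough for the former would waste most of its levels on the latter.

Decoding is LUT-exact, which is why the cine container (`write_cine()` /
`read_cine()`) is strictly lossless: multi-page deflate TIFF for frames,
8-bit PNG for the ROI mask, JSON for calibration and ground truth. A lossy
codec would perturb colors and therefore velocities.

## Tissue parameters

For frame *t* with perfused ROI pixels `P(t)`:

* `mean_v(t)` — mean of |v| over `P(t)`, and **0 when `P(t)` is empty**.
  The empty frame *is* the diastolic no-flow state; excluding it would bias
  TFV upward and make TRI = 1 unreachable.
* `area(t) = |P(t)| · s²` with pixel pitch `s` (cm).
* `intensity(t) = mean_v(t) · area(t) / roi_area` — algebraically the pixel
  sum of |v| divided by the ROI pixel count.

Cardiac cycles are delimited by successive systolic peaks of the intensity
signal (intensity pools area and velocity pulsation and is the smoother
signal; `detect_cycles(signal=)` exposes the choice). A peak needs
prominence ≥ 20% of the signal range and inter-peak spacing consistent with
a heart rate in `hr_bounds` (default 40–180 bpm). Frames before the first
and after the last peak are discarded. With fewer than two peaks the case
falls back, with a warning and a flag, to whole-trace extrema.

Over the union of complete cycles: TFV is the time average of `mean_v`, TPI
the time average of `intensity` (hence TPI ≤ TFV always), and TRI is
computed per cycle from the `mean_v` extrema and averaged across cycles —
the cycle-wise form matches Doppler convention and keeps TRI identifiable
when heart rate drifts; a cycle with `v_max = 0` contributes TRI = 0.

## Single-vessel parameters

Vessel candidates are the 4-connected components of the
temporal-maximum perfusion mask. "Known flow direction" is operationalized
as direction consistency ≥ 0.8: the fraction of signal-carrying frames in
which the component's modal velocity sign is stable. The measurement vessel
is the largest consistent candidate; its axis is the principal component of
the pixel coordinates, the Doppler angle is the angle between axis and beam
folded into [0°, 90°], and the diameter is mask area / axis length — an
average width, chosen over a single perpendicular profile because it
averages pixelation error along the whole vessel.

The spectral trace takes the *peak* |v| over the vessel per frame (the
spectral envelope is conventionally defined on the peak, approximating a
gate at the vessel center) divided by cos θ. Cases with θ > 60° are computed
but flagged `angle_valid = FALSE` rather than dropped — the validity
boundary is a property of the measurement, not of the case. At θ = 90° the
measurement does not exist and the case is excluded from SVFM with a
distinct error, while remaining fully eligible for DTPM; this asymmetric
exclusion mirrors clinical workflow.

FV is the time-averaged corrected trace over complete cycles (TAV of the
peak trace; whether the reference implementation uses TAV or time-averaged
*mean* is not documented anywhere we could find, so the convention is fixed
here and stated). RI uses PSV/EDV per cycle and is invariant to the angle
correction. VolF uses the corrected velocity (the uncorrected alternative
would make VolF angle-dependent, which contradicts its definition as a flow
volume).

## Cohort statistics

* Normality gate: Shapiro–Wilk at α = 0.05 per group; both groups must pass
  for Welch's t-test, otherwise Mann–Whitney (exact where R's
  implementation allows, normal approximation with tie correction
  otherwise). `compare_groups(test=)` can force either path.
* ROC: concordance AUC with ties counted ½, direction auto-oriented so
  AUC ≥ 0.5. The reported cut-off is the observed value maximizing Youden's
  J; ties break towards higher specificity, then the smaller threshold, so
  the cut-off is deterministic. At the cut-off,
  `acc = (sens·n₁ + spec·n₂)/(n₁+n₂)` holds exactly by construction.
  AUC significance against 0.5 uses the tie-corrected normal approximation
  to the Mann–Whitney statistic.
* Paired AUC comparison: DeLong's variance of the AUC difference from
  placement values, two-sided normal p. Each marker is oriented before the
  comparison (discriminative ability is direction-free). When the variance
  of the difference is zero — self-comparison, or any strictly monotone
  transform — the ROC curves coincide and p = 1 by definition; this
  degenerate branch is handled explicitly rather than returning 0/0.

## What the synthetic generator emulates

Each case is a 2-D phantom: a straight main vessel (length 0.3 cm) at a
prescribed Doppler angle with a parabolic cross-profile, two minor feeding
segments, and a shared raised-cosine cardiac waveform
`w(t) = p + (1−p)(1−cos 2πu)/2` with diastolic floor `p` (so the generated
TRI is `1 − p`). Rendered pixel velocities are **beam-projected**
(`v·cos θ`): that is what a scanner measures, it is what makes the
`1/cos θ` correction recover the same FV across renderings of one vessel at
different angles, and it reproduces the systematic underestimation of
oblique flow by the uncorrected tissue route. The cosine is clamped at 0.05
so a perpendicular vessel remains visible (and exercises the
"unmeasurable" SVFM path) instead of vanishing.

The construction is solved, not simulated: the main-vessel velocity scale
comes from the target FV; the minor-vessel scale from the target TFV (the
per-frame spatial mean is linear in it); the minor-vessel pulsatility from
the target TRI by a short fixed-point iteration on the composite trace; the
ROI pixel count from the target TPI. Ground truth is then *measured* from
the continuous, pre-quantization trace with the package's own cycle logic,
so recovery tests isolate exactly the decoding and segmentation error.

Per-label parameter distributions (`cohort_calibration()`) are matched to
published group summaries of malignant (n = 40) vs inflammatory (n = 29)
pancreatic lesions: TFV normal (the one parameter published as mean ± SD),
TPI/FV/VolF log-normal with the median matched exactly and the log-SD the
least-squares fit to the two quartiles, malignant resistive indices a point
mass 0.80 at 1.0 with a uniform(0.40, 0.85) lower tail (the published
quartiles are degenerate at 1.000 and leave the tail free; this tail
reproduces the published discrimination scale of the resistive indices),
inflammatory TRI logit-normal and inflammatory RI logit-normal with a 0.28
ceiling mass at 1. Within a case the four flow-scale parameters share one
latent quantile and the two resistive indices another (comonotone
coupling): one vascular bed, coherent hypo- or hypervascularity, and almost
always feasible joint constraints. Physical floors (TFV ≥ 0.15 cm/s,
FV ∈ [0.3, 10] cm/s) clip the marginal rather than rejecting the joint
draw — rejection would drag every comonotone median upward.

What the phantom does **not** emulate: speckle statistics and attenuation,
aliasing, wall filters and spectral broadening, vessel curvature and 3-D
geometry, ROI motion. Passing recovery tests therefore demonstrates that
the measurement chain is correct on clean, LUT-faithful data; it does not
certify performance on clinical recordings, where segmentation and angle
estimation face noise the phantom deliberately omits. The default noise
knob (`noise_sd`) is 0; decoding robustness to RGB perturbation is tested
separately.

## Numerical choices and degenerate inputs

* Chroma threshold 24/255; configuration-exposed.
* Peak prominence 20% of range; heart-rate bounds 40–180 bpm.
* Direction-consistency threshold 0.8; angle validity cap 60°.
* Acquisition defaults 15 Hz and 0.01 cm/px are configuration, not claims —
  the source recordings' values are not published.
* Encode ties between two LUT velocities fall to `findInterval`'s left-bin
  rule; decode distance ties resolve toward the smaller speed.
* Empty traces, constant traces, single-class label vectors, all-NaN frames
  and collinear vessel masks each raise a distinct classed error; pipeline
  wrappers convert them into reason-coded exclusions, never silent drops.

## Problem sizes

Test and acceptance runs use: 2000 replicate cohorts for the
binormal-AUC check; 200 cohorts for the AUC-oracle equivalence; 100 random
fields for the codec round trip; 50 rendered noiseless cases for parameter
recovery; 1000 null cohorts for the Type-I sweep of the paired AUC test;
100 parameter-level cohorts (40/29 each) for the qualitative group pattern.
Rendered-case checks run at the parameter draws' natural ROI sizes capped at
400 px a side; the cap binds only for the most hypovascular draws, whose
realized TPI the ground truth records faithfully.

## Known limitations

* The log-normal family cannot reproduce the published asymmetric IQRs
  cell-exactly; with it, roughly 8% of calibrated 40/29 cohorts fail to
  reach p < 0.05 simultaneously on all six parameters (the malignant VolF
  upper tail is the dominant cause). The published AUC *ordering* among
  parameters is likewise not implied by the group summaries alone and is
  not asserted by the tests — only discriminability of every parameter is.
* Diameter estimation from the mask, not a luminal profile, biases VolF for
  vessels a few pixels wide.
* The whole-trace TRI fallback (no detectable cycle) underestimates TRI for
  clips shorter than one cardiac cycle.
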