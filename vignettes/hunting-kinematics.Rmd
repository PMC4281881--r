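---
title: "Classifying larval zebrafish hunting bouts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying larval zebrafish hunting bouts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Larval zebrafish respond to small prey-like visual stimuli with a
specialized motor program: low-amplitude forward swims aimed at the prey and
j-turns, sustained unilateral tail bends that reorient the fish. In the
absence of prey they produce spontaneous swims of much larger tail-beat
amplitude. In head-fixed preparations only the tail moves, so the entire
behavioral readout is the tail's shape over time, recorded at 300 frames/s
on 300 × 300 px video. `preybout` implements the full quantitative chain for
such experiments:

1. **Tail digitization** — ridge-following tracker producing ~40 ordered
   midline points per frame (`track_video()`).
2. **Kinematics** — per-frame tail/tip angles, positions and curvature, and
   bout segmentation by thresholding the normalized, smoothed derivative of
   the tail bend angle (`compute_kinematics()`, `segment_bouts()`).
3. **Features** — 16 per-bout kinematic parameters (`extract_features()`).
4. **Classification** — an RBF-kernel SVM separating prey-capture from
   spontaneous bouts under fivefold stratified cross-validation, with
   accuracy-vs-parameter-count subset selection, prey-capture scoring and
   stimulus tuning curves (`cross_validate()`, `train_bout_classifier()`,
   `prey_capture_score()`, `tuning_curve()`).
5. **Calcium imaging** — pixelwise ΔF/F against a sliding 8th-percentile
   baseline, condition ratio maps, ROI responses and normality-gated
   two-group statistics (`compute_dff()`, `condition_ratio_map()`,
   `compare_groups()`).

Because no raw recordings ship with the package, a first-class synthetic
generator (`generate_bout()`, `generate_trial()`, `render_video()`,
`generate_fluorescence_movie()`) produces ground-truth traces, videos and
fluorescence movies on which every downstream stage is exercised and
validated.

# The synthetic generator defines the study conditions

The generator's class defaults are anchored to the published bout
statistics rather than chosen freely:

| parameter | prey_forward | spontaneous | j_turn |
|---|---|---|---|
| tip amplitude (fraction of tail length) | 0.17 | 0.48 | tan(45°)/1.5 ≈ 0.67 |
| beat frequency (Hz) | 15 | 8.6 (calibrated, see below) | — |
| bout duration (ms) | 180 | 280 | 2 × 80 ramp + hold |
| hold duration (ms) | — | — | 100–600 (uniform across bouts) |
| per-point jitter (fraction of tail length) | 0.005 | 0.005 | 0.005 |

Oscillatory bouts follow a sinusoid on the tail-tip deflection whose
envelope is flat until the first quarter-cycle and then decays
exponentially to 95% of the starting amplitude at bout end — a mildly
damped beat. The damping is deliberately weak so that the mean
peak-to-trough half-amplitude over a bout's cycles essentially equals the
`tip_amplitude` parameter: that is what makes the 17% / 48% class
amplitudes the generator's *ground truth*, recoverable by the analysis
chain rather than merely encoded in it. Across bouts, amplitude varies with
a 5% coefficient of variation, duration 10%, frequency 5% (truncated
Gaussian, mean one): tight, class-defining variability chosen so the
population statistics above remain sharp.

The bend shape grows linearly from the base for oscillatory swims (the tail
sweeps like a flexible rod pinned at the base), and as $s^{1.5}$ in arc
position for j-turns, weighting the bend toward the tip so the held tail
forms the eponymous J. With the linear profile a 45°-tip j-turn would hold
the tail's center of mass below the 20° bend criterion; the distally
weighted profile keeps the center-of-mass angle near 28° throughout the
hold, so a 300 ms hold registers as a ≥ 300 ms bend, matching how sustained
j-turn deflections present in real recordings.

**Spontaneous beat-frequency calibration.** The source experiments never
state a tail-beat frequency, but they report that the distribution of the
longest tail bend exceeding 20° peaks at 27 ms for spontaneous swims — one
beat half-cycle. For a sinusoidal deflection of amplitude $A = 0.48$ the
center-of-mass tail angle peaks at $\arctan(0.48) \approx 25.6°$, and the
time spent above 20° per half-cycle is
$(\pi - 2\arcsin(\tan 20° / 0.48)) / (2\pi f)$. Solving for a modal
frame count of 8 frames at 300 f/s (the 3.33 ms histogram bin containing
27 ms) and verifying numerically over the default jitter distribution fixes
$f = 8.6$ Hz. This is a calibration choice, not a measured value; the
forward-swim default of 15 Hz (a frame-synchronous quarter cycle at
300 f/s) is likewise a realism choice.

**What the generator does and does not emulate.** It reproduces the
class-separating kinematics (amplitudes, sustained bends, bout/rest
alternation), rendered video geometry (bright ~4 px FWHM tail stroke on a
dark noisy background), and ROI-localized, stimulus-tuned fluorescence
responses with Gaussian noise. It does not model an inextensible backbone
(lateral deflection is added to a straight axis, so a strongly bent tail's
arc length grows by up to ~11%), paramecium motion, eye or body rendering,
tail-beat frequency modulation within a bout, or photon shot noise. The
displacement-profile construction is what makes the horizontal tip
deflection exactly `tip_amplitude` × rest tail length — the property the
amplitude-recovery validation rests on. Passing tests therefore demonstrate
that the analysis chain recovers known kinematics through rendering,
tracking and segmentation; they do not certify performance on real video
artifacts such as pigmentation gaps, shadows or defocus.

# Tracking

Calibration measures the tail's width (FWHM of the perpendicular intensity
profile at the base) and contrast (profile peak minus the frame median) in
the first frame, then walks the tail once to set the step so a full tail
yields ~40 points. Per frame, the tracker extrapolates the next midpoint
from the last segment, samples a perpendicular intensity slice (bilinear
interpolation, 1 px spacing, length four tail widths), smooths it with a
Gaussian of σ = width/2, convolves with a Gaussian matched to the
calibrated width, and takes the argmax — refined to sub-pixel precision
with a parabolic fit, ties broken toward the predicted midpoint for
continuity. Tracking stops when the luminance change across the slice
(smoothed peak minus slice median) falls below 30% of the calibrated
contrast; this fraction is exposed as `stop_frac` because the source method
does not state a numeric threshold. Trailing points whose image intensity
falls below half the contrast are trimmed (they lie past the tip), the
polyline is lightly smoothed with endpoints fixed, and each frame is
resampled to exactly 40 points by arc length. The rest tail length is the
median tracked arc length over frames, which is robust both to per-frame
tip jitter and to the slight lengthening of strongly bent frames.

Frames with fewer than 10 points are flagged and carried as missing values;
a video with more than 10% flagged frames is rejected. Coordinates are
0-based pixels, origin top-left, x rightward, y downward.

# Kinematics and features

The rest axis defaults to the base-to-tip line of the frame whose
base-to-tip angle is the median over frames — a resting frame in any trial
that contains rest. For bout-only traces the axis should be supplied
explicitly (the axis of a trace that is mid-turn for most frames is not a
rest axis); `synthesize_labeled_bouts()` does so.

Signals: the tail angle is the deflection angle of the midline's center of
mass; the tip angle is a least-squares line through the last eight points;
positions are lateral deflections as fractions of tail length. The series
carries both `tip_position` (centroid of the last eight points — the
published definition used by feature f5) and `tip_deflection` (the distal
point itself). `bout_amplitude()` uses `tip_deflection`, because for a
linearly growing bend the last-eight-point centroid sits at ~92% of the
tip's deflection and would systematically understate the tail-beat
amplitude the generator defines; the distal point recovers it exactly.
Curvature is the per-frame maximum absolute three-point (Menger) curvature
over a stencil of one tenth of the point count on lightly smoothed points,
reported in units of 1/tail-length — the stencil and smoothing keep the
estimate stable under sub-pixel tracking noise while remaining exact on
circular arcs.

Bout segmentation takes the first derivative of the tail angle, smooths it
with a 5-frame moving average, normalizes by its median absolute deviation
(robust to bout-heavy trials), marks frames above 3.5 scale units active,
closes gaps shorter than 15 frames (the derivative crosses zero at every
beat extremum) and drops runs shorter than 10 frames (the shortest real
bouts last tens of milliseconds). Missing frames are bridged by linear
interpolation for segmentation only and excluded from per-bout statistics.
With long j-turn holds the derivative is genuinely quiet for hundreds of
milliseconds, so a pure derivative threshold can split a ramp-hold-release
j-turn into its two moving phases — a known limitation of this segmentation
rule, shared with the original.

Peak counting (f2) uses the rectified tail angle, so left and right beats
both count, with a 2° prominence floor to suppress rest noise;
`detect_peaks()` itself operates on the signal as given (a three-cycle
sinusoid has three peaks). f6, the mean frame spacing of those peaks, is
undefined for bouts with fewer than two peaks and is imputed with the
training-set median at classification time. The frequency bands for f7/f8
are 5–30 Hz (medium: beat-frequency oscillations) and 0.5–5 Hz (low:
j-turn holds); the source lists the bands by name only, so both are
config-exposed. The tail-vs-tip comparisons f9/f15 are signed means, f10 is
evaluated at the frame of maximum absolute tail angle, and f5/f13 take the
absolute value of the per-bout mean so that all magnitude-like features are
mirror-invariant (a bout's side carries no class information).

# Classification

Folds are stratified by class and, within class, ordered by the first
feature and dealt serpentine-style — this realizes the source's "groups of
approximately equal mean" while keeping fold sizes within one bout per
class; because the assignment is keyed on feature content rather than row
order, cross-validation is invariant to permuting the training set. The
SVM is `e1071::svm` (libsvm) with an RBF kernel, `cost = 1` and
`gamma = 1/n_features` on features standardized by training-fold
statistics — library-conventional defaults, config-exposed, as the source
states no hyperparameters. Both pooled accuracy and mean-of-folds accuracy
are reported since the source does not say which its headline number is.
Parameter selection cross-validates nested prefixes of a ranked candidate
list (default ranking: single-feature CV accuracy) and picks the smallest
count within 0.5 percentage points of the maximum. Prey-capture scores are
the percentage of trial frames inside prey-capture-labeled bouts; tuning
curves normalize each larva's scores to its own maximum (in percent) before
averaging, and `exclude_low_responders()` implements the 30%-score
screening rule for the reference stimulus.

# Imaging

The ΔF/F baseline is, per pixel, the 8th percentile of raw fluorescence
over a centered 25-frame sliding window, truncated at the movie edges;
percentiles interpolate linearly between order statistics (the
`stats::quantile` type-7 convention — the source does not state one, so the
convention is documented and the test oracle uses the same). Note an
inherent property of percentile baselining: under zero-mean noise of
standard deviation σ the 8th percentile sits ≈ 1.4σ below the true
baseline, inflating ΔF/F by ≈ 1.4σ/F₀; the ROI-recovery test accounts for
this bound. Condition ratio maps divide the per-pixel maxima of the two
ΔF/F segments, masking pixels whose pre-segment maximum is below 0.05 to
avoid dividing by noise. Movies are assumed registered;
`detect_translation_drift()` warns when phase correlation against the first
frame moves by more than 2 px. Group comparisons follow the source's gate:
Jarque–Bera on each sample (implemented from its closed form, as no
installed package provides it), a two-sample t-test when both samples are
consistent with normality at α = 0.05, the Wilcoxon rank sum test
otherwise, with Levene's variance test reported alongside.

# Numerical choices and degenerate inputs

* Zero-amplitude bouts are allowed (straight tail); negative amplitudes,
  non-positive durations and frequencies are rejected.
* Amplitude estimation pairs alternating extrema detected with a hysteresis
  of 25% of the bout's deflection range; unconfirmed trailing extrema are
  dropped (partial final swings would bias the mean), and single-deflection
  bouts (j-turns) fall back to the maximum absolute deflection.
* Zero-variance features are dropped from training with a warning; ties at
  the SVM decision boundary resolve by libsvm's deterministic rule.
* All generators are bit-reproducible under a seed; batch helpers derive
  per-bout substreams from one master seed, kept within R's 32-bit integer
  range.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data at the study's
design points: a 248 + 121-bout training set for cross-validation, 100
rendered-and-tracked bouts per class for amplitude recovery, 200 bouts for
the bend-duration distribution, 100 two-bout trials for boundary recovery,
1,000 random pixel traces for the baseline oracle, and 500 samples per
class for the overlapping-Gaussian cross-validation check.

# Known limitations

* The tracker assumes a single, head-embedded animal with a fixed base
  point and a bright tail on a dark background; free-swimming fish, eye
  tracking and real-time operation are out of scope.
* Derivative-threshold segmentation can split long-hold j-turns (above).
* The synthetic tail is a displacement profile, not an inextensible
  backbone, and the fluorescence model omits shot noise and motion
  artifacts; conclusions about real-data performance require real data.
* Registration of imaging stacks is assumed done upstream.
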