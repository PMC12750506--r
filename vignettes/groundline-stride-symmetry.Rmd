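---
title: "Groundline-referenced stride symmetry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groundline-referenced stride symmetry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideline)
```

## What the package measures

At trot the trunk of a horse oscillates vertically twice per stride, once
for each diagonal limb pair. Lameness shows up as an asymmetry between the
two half-cycles: differences between the two per-stride maxima (push-off,
**Maxdiff**) and between the two minima (impact, **Mindiff**) of a trunk
landmark's vertical displacement signal (VDS). Measuring VDS from a
single 2D video requires a ground reference in the image — the
**groundline** — and `strideline` is built around estimating that line
dynamically from the hoof keypoints themselves, so that no manual marking
or calibration object is needed and the camera may move.

The package contains two halves that validate each other: a kinematic
simulator with exact ground truth, and the measurement pipeline. Nothing in
the pipeline reads simulator internals; it sees only pixel keypoints and
visibility flags.

## The simulator

### Trunk model

Each trunk landmark (eye, withers, croup; a back point is carried but not
analysed) follows

$$z_k(t) = z_{0k} - A_k \cos(4\pi f t + \phi_k) + a_k \sin(2\pi f t + \psi),$$

with stride frequency $f$ (default 1.25 Hz), second-harmonic amplitude
$A_k$ (default ≈ 30 mm) and a stride-frequency component $a_k$ that is the
injected asymmetry. This is the minimal kinematic form in which Maxdiff and
Mindiff are independent quantities: with the default phases, the
closed-form per-stride values are $\mathrm{Maxdiff} = 2a\cos\psi$ and
$\mathrm{Mindiff} = 2a\sin\psi$. `oracle_symmetry()` evaluates them by
dense-grid extremum search (10^4 points per stride) on the closed form, so
every recovery test in the package compares against an oracle that is
independent of the measurement path.

### Limbs, belt and cameras

Diagonal pairs (LF+RH, RF+LH) move in anti-phase with duty factor 0.45.
During stance the hoof is exactly on the ground plane and is carried
backwards at belt speed (default 4.8 m/s); the swing is a half-sine lift
(80 mm apex) with a constant-velocity forward reset. Only the stance
geometry and event timing matter downstream, so the swing path is
deliberately simple. The left-fore stance onset is placed at stride phase
0.875, which centres the four trunk extrema inside the two stride halves.

All 16 landmarks are placed in the sagittal plane (y = 0). Trotting horses
largely single-track, the pipeline is strictly two-dimensional, and this
choice makes the geometric ground truth exact (stance hooves project onto
the true groundline to machine precision). The cost is that left/right
hoof parallax — two slightly separated ground traces seen by a real
camera — is not emulated; the support-point averaging described below would
cancel its first-order effect, but the simulation does not test that.

Cameras are ideal pinholes (no lens distortion: keypoints, not pixels, are
the input contract). The default rig has six stationary cameras — a
perpendicular side view at three heights (50/100/160 cm), 50° oblique
front and rear views, and a left-side view at 250 cm — plus a handheld
side camera. Handheld motion is a pure translation: a seeded 1 Hz sinusoid
(default 20 mm vertical, 60% of that horizontally) plus low-pass-filtered
jitter (≤ 3 Hz, 15% amplitude), emulating an operator stepping on the
spot. Orientation shake is not modelled. Detection noise is i.i.d.
Gaussian in pixels and occlusion is i.i.d. per keypoint-frame — a real
pose network's errors are correlated in time and anatomy, so passing under
this noise model does not certify behaviour under structured failures.

At the default focal length (950 px at 3 m) the image scale is about
0.32 px/mm, so the standard 1 px noise level corresponds to ~3 mm of
keypoint uncertainty.

## The measurement pipeline

### Stance detection

A stance hoof still travels tens of px/frame horizontally with the belt
(along a slanted trace for oblique views), so the speed criterion is
applied to the hoof's perpendicular residual to a ground trace. Detection
runs twice: first against a coarse per-hoof trace (a quantile
least-absolute-residual line fit to the hoof's pixel cloud, τ = 0.75 —
the lower envelope that the hoof rides during stance), then, once a
groundline estimate exists, against that line. A frame is stance when the
running-median (3 frames) residual changes by less than 1.5 px/frame —
the *forward* difference, so the touchdown frame, which stops abruptly,
is included — and the hoof sits within 5 px of the reference. Runs
shorter than 3 frames are dropped; gaps of ≤ 2 frames are bridged. On
clean synthetic side views this recovers the duty factor to within one
frame per stride and overlaps the true stance flags with Jaccard ≥ 0.94 at
1 px noise.

### Groundline estimation

Per frame, all stance hooves are averaged into one support point
(duplicate-point leverage from a diagonal pair would otherwise tilt the
fit), and a least-absolute-residual line is fitted to the support inside a
31-frame sliding window — about one stride, so the support composition
stays balanced across both diagonals. The L1 fit is IRLS with a two-point
polish (the L1 optimum interpolates two data points; the polish searches
pairs among the smallest-residual points), which matches exhaustive
two-point minimisation to < 0.01° on small point sets.

Fast image translation (a bouncing camera) cannot be followed by a
one-stride window, and worse, it masquerades as a tilt because the stance
hooves sweep in x while the line translates. The estimator therefore
separates time scales:

1. the whole-recording L1 line (immune to bounce, which averages out) fixes
   a reference;
2. the per-frame translation track — the smoothed perpendicular residual of
   the support to that reference — is removed from the support;
3. the sliding-window fit runs on the translation-free cloud and recovers
   the local angle;
4. the translation track is re-estimated about the local fit and restored
   as a per-frame offset correction.

The track is smoothed by a zero-phase Butterworth low-pass whose bandwidth
adapts to the camera: 3 Hz when the track shows real band power (0.3–3 Hz
amplitude above 1.5 px — a moving camera; the threshold is several noise
standard deviations above a static track and far below any visible
bounce), otherwise 1 Hz, which removes tracking noise from the stride
passband of a static recording. Support gaps (suspension moments) are
bridged by spline continuation rather than linearly, since linear
interpolation of a curving bounce aliases stride-frequency sidebands into
the passband. Under a pure 7 px, 1.1 Hz image translation the filtered
withers VDS changes by < 0.15 mm MAE.

Frames with fewer than two support points in the window are flagged
invalid and filled by linear interpolation of the neighbouring line
parameters.

### Rectification and VDS

`rectify()` applies the rigid rotation about the line's foot point that
levels the groundline — per frame, or using the central frame's
transformation throughout (the fixed-groundline control treatment). The
VDS itself is computed directly as the signed perpendicular
point-to-line distance per frame (positive above the line); for a constant
line the two formulations are identical because the transform is rigid.

Calibration divides the known withers height by the median visible
withers-to-groundline distance (median, not mean: robust to the
oscillation extremes), making calibrated VDS exactly invariant to camera
zoom. At least 50% withers visibility is required.

### Stride frequency and filtering

The stride frequency is estimated from a limb-derived signal (the
reference hoof's vertical trace) by periodogram peak search in 0.5–2.5 Hz
on a Hann-windowed, zero-padded copy. Because the trunk's dominant line
sits at $2f$, a candidate peak is validated by requiring periodogram
support at its second harmonic; among supported candidates the most
powerful wins, and a pure tone (no harmonic) falls back to the strongest
band peak. A signal with no peak above 10× the median power is an error,
not a number.

Filtering is a 3rd-order Butterworth high-pass with cutoff 5% below the
estimated stride frequency, applied forward and backward. Zero-phase
filtering is a deliberate choice: extremum timing feeds the stride split,
so phase distortion is unacceptable; the amplitude response applies twice
(gain exactly 1/2 at the cutoff, 0.99 at the $2f$ trunk line, 0.26 at a
1 Hz bounce remnant). A consequence worth stating plainly: the asymmetry
component at $f$ itself is passed at $|H|^2 = 0.576$, so a kinematic
Maxdiff of $2a$ is measured as $\approx 1.15a$. The package treats the
*filtered* closed form as the recovery target —
`oracle_symmetry(cutoff = )` applies the exact discrete two-pass gains to
the harmonics — rather than inflating measurements back; the agreement
analyses compare identically filtered conditions, so the attenuation
cancels there.

Gaps are imputed before filtering by local harmonic regression at the
known stride frequency (intercept, drift, three harmonics, fitted over the
surrounding two stride periods): the VDS is band-limited, and polynomial
interpolation would leave millimetre-scale errors that the IIR filter
rings into neighbouring strides. Imputed frames are re-masked afterwards;
a 3-frame hidden gap changes neighbouring strides' Maxdiff by ~0.1 mm.
The first and last 1/cutoff seconds are flagged warm-up; the series is
reflect-padded inside the filter so the edge transient itself is
negligible, and strides touching the warm-up span are excluded.

Alongside the high-passed series a low-passed copy (cutoff $3f$) is kept
for extremum reading: the gait signal is band-limited to the first two
stride harmonics, so suppressing detector noise above $3f$ halves the
per-stride metric noise, while the mild attenuation of the second harmonic
is common to both maxima (and both minima) and cancels exactly in the
differences.

### Stride segmentation and symmetry

Stride boundaries are successive stance onsets of a fixed reference
forelimb (left fore by default; swapping the reference negates both
metrics exactly). Two refinements make the split robust at 30 fps, where
the four extrema sit only ~6 frames apart:

* Onsets are projected onto a regular grid (robust line fit of onset frame
  against stride index) — on a treadmill the period is stable, and
  individual onsets jitter by a few frames under noise.
* The grid is then shifted (by at most ±T/4, preserving the left/right
  identity) so that boundaries sit centred in the maximum-to-minimum gap
  of the observed extrema pattern. Stance-onset detection is structurally
  a touch late, which would otherwise park boundaries on top of a
  minimum and make the half-split ambiguous.

A stride is excluded — never imputed — when it touches the warm-up span,
deviates more than 40% from the median duration, contains any frame with
the target keypoint hidden, or fails the shape check (exactly two
prominent maxima and two prominent minima, prominence = upper 30% of the
stride's range, merged within T/4; window endpoints count only if the
boundary sits essentially on an extremum). Extrema are located per stride
half and refined by a least-squares parabola over ±3 frames, halving
quantization error at the ~12 samples per oscillation cycle that 30 fps
provides.

Trials are contiguous blocks of 17 valid strides (a trailing remainder of
at least half a trial is kept); trial metrics are arithmetic means of the
member strides.

### Agreement battery

`match_strides()` pairs strides across synchronized recordings greedily by
temporal overlap (≥ 50% of the shorter stride, each stride used once, ties
to the earlier stride). `agreement()` reports n, mean signed difference,
SD, 95% limits of agreement (mean ± 1.96 SD; 1.96 rather than a
t-quantile, the standard large-n Bland–Altman practice), MAE, and a
normal-approximation CI for the MAE (z · sd(|d|)/√n, z = 2.576 at the
default 99%; at the sample sizes involved the approximation is exact for
practical purposes). Difference directions are fixed once:
estimated − fixed, and handheld − stationary.

`evaluate_session()` runs the three analyses on a simulated session:
per-frame groundline angle error against the camera-geometry reference
(per stationary camera and pooled); stride-level Maxdiff/Mindiff agreement
between the dynamic- and fixed-groundline pipelines on identical
recordings, pooled over the stationary cameras per keypoint and overall;
and the handheld-vs-stationary comparison at stride and trial level. It
also closes the stride accounting: the theoretical count is
(analyzable span × f) − 1 — a span of S seconds at random phase holds
S·f − 1 complete onset-to-onset strides — and detected + excluded strides
close to it within two edge strides per recording.

## Study conditions used by the tests

The validation suite and `scripts/acceptance.R` use an eight-horse cohort
(stride frequency 1.18–1.32 Hz, belt speed 4.5–5.2 m/s, withers height
154–168 cm, trunk amplitudes 26–36 mm, asymmetries 0–5 mm with a quarter
of horses symmetric), 40 s per recording, the seven-camera rig, 1 px
keypoint noise, and an occlusion rate of 0.00105 per keypoint-frame —
chosen so that a ~24-frame stride is lost with probability ≈ 2.5%, which
puts the stride-detection failure rate in the low single digits of
percent. Single-recording tests use 20–60 s. These sizes keep the whole
suite within a few minutes while leaving every pooled statistic with
thousands of strides.

Typical results under those conditions: pooled groundline angle MAE
≈ 0.07° (bias < 0.02°); dynamic-vs-fixed stride MAE ≈ 0.3 mm with |mean
signed error| < 0.02 mm; handheld-vs-stationary stride MAE ≈ 2 mm
shrinking to ≈ 0.5 mm at trial level (ratio ≈ 0.25, consistent with
averaging 17 strides); failure rate 2.5–3.5%.

## Limitations

* The simulator is strictly periodic and sagittal: no speed drift, no
  lateral sway or parallax, no skin-marker-like soft-tissue artefacts, no
  lens distortion, and detection errors are white and Gaussian. Results
  under this model bound what the estimators can do, not what any
  particular pose network delivers.
* Asymmetry recovery is reported against the filtered closed form; users
  comparing absolute Maxdiff/Mindiff across systems with different filter
  chains must account for the passband of each.
* The statistical power of a single ~50-stride recovery run at 1 px noise
  is limited (per-stride metric SD ≈ 1.4 mm, so the mean carries a
  ≈ 0.2 mm standard error); cohort-level statistics are the intended
  readout.
* The left/right identity of the stride halves is taken from the simulator
  labels via the reference forelimb; with real data that identification
  must come from the pose network.
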