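---
title: "Methods: keypoint kinematics, exercise recognition and feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keypoint kinematics, exercise recognition and feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinerehab)
```

`kinerehab` implements a complete tele-exercise analysis chain for
monocular pose-estimation output: 33 body landmarks per frame in the
BlazePose topology, with normalized image coordinates (origin top-left, y
down), a relative depth channel and a per-landmark visibility score. This
vignette explains the models and procedures, the tunable parameters, what
the synthetic generator does and does not emulate, and the numerical
choices that shape the results.

## Coordinate conventions and the depth channel

All geometry defaults to the frontal image plane `(x, y)`. Monocular depth
estimates are far noisier than the image-plane coordinates, so `z` is
opt-in everywhere: it only supplies the *sign* of trunk rotation and a
cosmetic channel in the generator. Consequences run through the package —
angles are planar, the upright-spine checks of the frontal-view exercises
are not attempted (they would live in the unobservable sagittal plane),
and the variance-based choice of segmentation signal considers x/y traces
only.

## Body-centering geometry

Pose models work best when the subject fills the frame, so a personalized
crop box is calibrated once per session: its center is the median hip
midpoint over a 1 s calibration window, and its half-side is
`scale × RDS`, where the reference distance RDS is the mean of the two
shoulder-to-index-finger arm lengths. The defaults (`scale = 2`, square
box, visibility threshold 0.5, essential set = nose, shoulders, hips,
knees, ankles) are conventions: they keep a standing adult with raised
arms inside the box with margin. Calibrating once — rather than per frame
— makes the box immune to pose jitter.

## Motion and pause detection

The percentage amplitude modulation between consecutive samples,
`m[i] = 100 |x[i+1] − x[i]| / max(|x[i]|, eps)`, is thresholded at 30%.
A design subtlety: for a median-centered movement signal sampled at
30 fps, `m` exceeds 30% only near zero crossings — about a fifth of the
samples during genuine motion, independent of amplitude — so a strict
majority vote in a sliding window would never fire. `detect_activity`
therefore scores a sample active when at least a fraction `vote_frac`
(default 0.1) of modulation values in a 0.5 s centered window exceed the
threshold *and* the local signal range exceeds `amp_min` (default 0.01
normalized units). The amplitude floor keeps pose-estimation noise on a
resting subject from registering as activity, which a purely relative
measure cannot do: noise divided by noise is order one at any scale.
Runs shorter than 0.5 s (active) / 1 s (pause) are merged into their
neighbours, yielding a debounced partition of the trace.

## SSA detrending

Hand-held recordings superimpose a slow common-mode drift on every
landmark. Singular spectrum analysis embeds the signal in an `L × K`
trajectory matrix (default `L = min(n/2, 2 fs × expected period)`, so one
window holds two repetitions), takes the SVD, and reconstructs 12
summable components by anti-diagonal averaging; residual energy beyond
the leading terms is folded into the last component so the components sum
to the input to machine precision. Components are grouped by rule:
*trend* = dominant discrete frequency below 0.1 Hz (or below 1.5 spectral
bins, whichever is larger — a component slower than the resolution can
only appear in the first bin) with at least 10⁻⁴ of the energy;
*noise* = under 1% of the energy; *periodic* = the rest. Claiming trend
before the energy gate matters: the secondary SVD terms of a ramp are
individually small but must be subtracted with it. Detrending simply
subtracts the trend reconstruction and is only applied when the recording
is flagged hand-held (`camera_fixed = FALSE`); w-correlation grouping
would be a reasonable alternative rule but is not the default.

## Period estimation and repetition segmentation

The repetition period is read from the autocorrelation of the
mean-centered signal, searched between 0.5 s and 10 s. Three numerical
choices make this robust at realistic noise: the acf is smoothed with a
short centered window (symmetric, so a symmetric peak does not move); the
`1/n` taper of the sample acf is divided out (bounded at 2×) because its
downward slope otherwise drags flat peaks toward smaller lags; and among
peaks reaching 85% of the band maximum the *smallest lag* wins, which
prefers the fundamental over its multiples while ignoring sub-maximal
noise wiggles. A parabolic refinement interpolates between lags. Signals
without a qualifying peak (normalized height ≥ 0.2) raise an "aperiodic
signal" error rather than returning a guess.

Repetitions are cut at successive low-valued minima of the lightly
smoothed signal — every exercise profile returns to its rest posture
between repetitions, so rests are extrema; if the trace starts at its
maximum instead, the signal is flipped first. Boundary candidates closer
than half a period are merged, segments must last between 0.5 and 1.5
periods, and a segment must sweep at least 30% of the signal's range —
the amplitude gate that stops a quiet stretch between two rest minima
from counting as a repetition. A trailing half-executed repetition is
dropped. `first_cycle` applies the same anchoring without a known period
and returns the earliest rest-to-rest lobe; it is what lets the live
engine recognize an exercise after a single execution period, when the
autocorrelation cannot yet see two cycles.

Which signal drives segmentation is itself a choice: the maximum-variance
basic-keypoint trace among the image-plane axes. Side steps are the
exception — the legs alternate, so a single ankle sees every *second*
step; the combined lateral deviation of both ankles makes each step one
cycle.

## Joint angles and ROM

Angles use the cosine formula at the middle vertex of a landmark triplet,
clamped into [0, 180]°. Frames where any triplet landmark drops below
visibility 0.5 are linearly interpolated; above 10% missing the series is
rejected. Two measurement conventions cover the repertoire: abduction and
rotation are *excursions* from the rest posture, flexion measures are the
attained maximum of a series that is already a flexion angle. Per-rep
extrema are read at the 2nd/98th percentiles of the segment rather than
the raw extremes: the raw maximum of ~100 noisy samples is biased upward
by several degrees at realistic landmark noise, while the robust read is
insensitive both to single-frame spikes and to a boundary misplaced by a
few frames (the profile spends almost no time within a fraction of a
degree of its peak, so the trim costs ~0.1% of the ROM). For ROM
measurement the triplets use distal endpoints — wrist rather than elbow,
ankle rather than knee — because doubling the lever arm halves the
angular effect of landmark jitter; the guideline checks keep the
anatomical triplets since the elbow and knee angles are the quantities
being checked.

Trunk rotation and forward flexion are frontal-plane approximations from
foreshortening: rotating the trunk shrinks the apparent shoulder width by
`cos(theta)`, bending forward shrinks the apparent pelvis-to-shoulder
height the same way, so `theta = acos(apparent / calibrated)` with the
calibration taken from the first 0.3 s of the trial (rest posture). The
projection cannot distinguish flexion beyond 90°, which is why the
generator's forward-bend template stays at 45° even though adult spinal
flexion norms sit around 100°. The rotation sign, when wanted, comes from
which shoulder moves toward the camera.

The median of per-repetition maxima summarises a trial; dividing by the
normative table (AAOS goniometer values; Hemmerich-style squat norms)
gives the reported ratio, and `omega = ROM / repetition duration` the
angular velocity.

## Guideline checks

Each exercise carries geometric form rules evaluated per repetition
against a relative tolerance (default 0.15, clamped to the 0.10–0.20 band
used when scoring repetitions as correctly executed): extended elbows
during shoulder abductions and extended knees during forward bends
(minimum angle ≥ 180°(1 − tol)); arms perpendicular to the body axis
during trunk rotation (the arm is compared to the mid-shoulder-to-mid-hip
axis, which is exactly vertical by construction, rather than to a
hip–shoulder triplet that carries a ~9° geometric offset at rest); and
knees behind the toes during squats, approximated in the frontal plane as
the knee landmark's excursion past the toe along the foot direction,
scaled by foot length. Trunk rotation additionally runs a coordination
check: the cross-correlation lag between the shoulder-width trace and the
wrist-spread trace (shoulder contribution removed, so it isolates the
arms) should show the arms trailing the trunk; if every pairwise lag is
below 0.15 periods the body is rotating as one block and the
corresponding correction is raised.

## Recognition: features, PCA, classifiers

Five basic keypoints represent the body regions: the virtual mid-hip
point for the torso, the wrists for the arms, the ankles for the legs —
distal points carry the most motion. Their x/y/z traces give 15 signals;
per repetition each contributes 12 time-domain features (mean, max, min,
RMS, variance, standard deviation, crest factor, kurtosis, skewness,
median, peak-to-peak, energy — the last three chosen as the most
conventional completions of the set) and 7 features of the Hann-windowed
periodogram over [0, fs/2] (mean, max, total, standard deviation, peak
frequency, kurtosis, skewness), for 19 × 15 = 285 values in a fixed
order. Degenerate inputs have defined conventions: crest factor 1 and
zero skewness/kurtosis for constant signals.

Features are z-scored before PCA (they mix units and scales), and the
smallest leading set of components reaching 90% cumulative variance is
retained — a rule rather than a fixed count, since the count is
data-dependent (on the default synthetic corpus it lands in the
twenties-to-thirties). Five classifiers are compared — random forest (100
trees), linear / polynomial (degree 3) / RBF SVMs at cost 1, and a
decision tree — with all scaling and PCA fitted on the training rows
only. Splits are subject-wise: whole subjects are drawn into the test set
until its repetition count is nearest the target fraction, and the
absence of train/test subject overlap is re-asserted inside the
evaluation path. Metrics (accuracy, macro-averaged F1, precision,
sensitivity, specificity, timings) are computed from the confusion
matrix; k-fold cross-validation on the training set is optional. A
permuted-label control should and does collapse to five-class chance.

## Session engine

The engine is a pure fold over frames: `step(state, frame)` returns the
new state plus messages, so a replay is deterministic and testable.
From `WAIT_FULL_BODY` the user is prompted until every essential landmark
has been visible continuously for the calibration window; the crop box is
then computed and the session idles. Activity on the segmentation signal
moves to `RECOGNIZING`; once one completed cycle exists (via
`first_cycle`, aligned rest-to-rest exactly like the training windows)
the classifier predicts the exercise, the counter starts at zero, and
`TRACKING` counts completed repetition segments, re-estimating the period
as the window grows. Each completed repetition is checked against the
guidelines; a correction message repeats every evaluation cycle while its
violation latches and clears after a clean repetition. A trailing pause
of 3 s suspends to `IDLE` (counter retained) with an immediate motivation
nudge, and further nudges every 5 s; two consecutive disagreeing
predictions announce a new exercise and reset the counter. Losing the
subject for over a second routes any mode back to the full-body wait.
Evaluations run every 0.5 s of stream time with a 3 s recognition
fallback window; all thresholds are `session_config()` parameters.

## The synthetic generator

The generator is the package's study population. A skeleton of normalized
segment lengths (default: 0.22 trunk, 0.25 arm, 0.31 leg, placed around a
pelvis at (0.5, 0.6)) is driven by raised-cosine joint-angle profiles,
`theta(t) = rom (1 − cos(2 pi t / period)) / 2` — C¹-smooth, with
unambiguous rest minima for segmentation anchors. Side steps alternate
single-leg hip abduction; shoulder abductions raise both straight arms;
trunk rotation renders as shoulder-width foreshortening with a signed
depth offset and the arms trailing by 0.2 periods (a coordinated rotation
— the `unified_trunk_rotation` error removes the lag); forward bends
shorten the apparent trunk; squats build the legs with an outward thigh
fold and a capped shank lean so that clean form keeps the knees behind
the toes. Landmark noise is i.i.d. Gaussian per coordinate (default
0.003 normalized units, mimicking pose-model jitter), camera drift is a
shared random walk — exactly the common-mode artifact SSA detrending
removes — and `partial_body` pushes the lower body out of frame.
`make_dataset` draws per-subject skeleton scale (±5%), ROM (±10%) and
period (±15%) jitter around per-exercise templates (SS 40°/2 s,
SA 150°/2.5 s, TR 45°/3 s, FB 45°/3 s, SQT 80°/2.5 s), chosen to sit in
the ranges a mixed trainer/patient population produces.

What the generator does *not* emulate bounds what passing tests show:
there is no soft-tissue artifact, no pose-model failure mode correlated
with clothing or lighting, no out-of-plane limb motion beyond the
foreshortening constructions, no inter-repetition variability within a
trial, and class geometry is cleaner than video-derived data — which is
precisely why the synthetic corpus is linearly separable and the
interesting classifier claims are *relative* (ordering of classifiers,
collapse under permuted labels), not absolute accuracies on real
recordings.

## Problem sizes and defaults used in the shipped checks

The test-suite and acceptance script run at desk scale, chosen so the
properties they probe are already stable: a 20-subject corpus with six
repetitions per exercise (600 repetitions) for classification, ROM
recovery over a {20, 40, 60, 90}° × {2, 3, 4} s grid at noise 0.003,
period recovery over 108 seeded sinusoid trials, repetition counts for
k = 1…10, and the scripted demonstration session (idle → two side steps →
pause → bent-elbow shoulder abductions → clean ones). Every number the
README or this vignette mentions is computed by those checks at run time.

## Known limitations

- Depth is untrusted by design; any assessment that genuinely needs the
  sagittal plane (spinal alignment, true knees-over-toes geometry) is
  either skipped or a declared frontal-plane approximation.
- Foreshortening-based measures saturate at 90° and lose sensitivity near
  0° (the derivative of `acos` diverges), inflating small-angle noise.
- The repetition model assumes quasi-periodic, rest-separated movement;
  free-form or continuous motion will not segment.
- The classifier bundle is only valid for the feature specification it
  was trained with; `load_model` refuses mismatched bundles.
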