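---
title: "Methods: comparing clothing-mounted and body-worn accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing clothing-mounted and body-worn accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabricmotion)
```

## The problem

Accelerometers sewn into everyday garments would make long-term physical
activity monitoring far less obtrusive than strapping devices to the skin.
The open question is how faithfully a clothing-mounted sensor reproduces
what a body-worn sensor at the same anatomical site records, given that
fabric lags, swings, shifts and rotates relative to the limb underneath.
`fabricmotion` implements a reusable pipeline for this comparison: paired
tri-axial streams (in units of g, 50 Hz by default) are synchronised,
rotated into a common gravity frame, correlated activity by activity under
increasingly aggressive corrections, and finally pushed through a simple
activity classifier so the *practical* agreement between the two sensing
routes can be tabulated.

## Signal model and pipeline stages

### Synchronisation markers

The wear protocol embeds markers directly in the acceleration signal: a
jump at the start and end of each recording (a distinctive high-magnitude
spike) and four synchronous taps on each sensor pair.  `detect_jump_marker`
returns the index of the magnitude maximum inside a search window, with a
configurable 2 g floor below which no marker is declared;
`detect_taps` returns the `n` largest local maxima separated by at least
0.2 s.  `coarse_align` shifts the two streams so their jump indices
coincide and trims to the common overlap.

### Residual lag by normalised cross-correlation

Cloth dynamics introduce an additional, activity-dependent delay between
the garment channel and the limb.  `estimate_lag_xcorr` scans integer
shifts $k \in [-K, K]$ and computes the Pearson correlation of the
overlapping samples at each shift,

$$\hat\ell = \arg\max_k \; r\!\left(x_{1:n-k},\, y_{1+k:n}\right),$$

reporting the maximising shift, the peak correlation, and the delay in
seconds ($\hat\ell / f_s$; 38 samples at 50 Hz is 0.76 s).  Three
numerical choices matter:

* **Normalisation.** Pearson-style normalisation per shift makes the
  estimate invariant to the amplitude scaling between channels — garment
  peaks are systematically sharper and larger than body peaks, so a raw
  sliding dot product would be biased.
* **Tie-break.** Exact ties resolve toward the smallest $|k|$ (shifts are
  scanned in increasing $|k|$ and a new maximum must strictly exceed the
  incumbent), favouring the null hypothesis of synchrony and making the
  estimator deterministic.
* **Estimation axis.** The y (gravity) axis is the default because it
  carries the strongest activity signal; it is configurable, and
  `"magnitude"` is available when orientation is untrusted.

The search half-range defaults to 2 s: garment lags observed in wear data
are sub-second, so 2 s bounds the search while tolerating looser garments.
`apply_lag`/`align_pair` then trim to overlap-only samples — no fabricated
values enter downstream statistics.

### Gravity alignment (Rodrigues rotation)

Mounting differences leave a fixed orientation offset between the sensors
in a pair.  Each stream is rotated so its estimated gravity direction
$\hat g$ maps onto $(0, 1, 0)$ using the axis–angle closed form

$$R = I + \sin\theta\,K + (1 - \cos\theta)\,K^2,$$

with axis $k = \hat g \times e_y / \lVert \hat g \times e_y \rVert$
(perpendicular to both), angle $\theta = \operatorname{atan2}(\lVert \hat g
\times e_y \rVert, \hat g \cdot e_y)$, and $K$ the cross-product matrix of
$k$.  Degenerate cases are handled deterministically: a cross-product norm
below $10^{-12}$ yields the identity (parallel) or a 180° rotation about a
fixed perpendicular axis (antiparallel).  Rotation about gravity itself
(heading) is unobservable with an accelerometer alone; it is left
uncorrected, which caps the x/z-axis correlations independently of any
garment effect.

Two gravity estimators are provided.  `static_window` (default) averages
over the lowest-variance 2 s window — the most static stretch — because
means taken over dynamic activity are biased along the movement axis.
`low_pass_mean` averages a 0.25 Hz Butterworth-low-passed signal over the
whole stream; it is the default for the *classification* stage, where the
record spans several postures and locking onto a single static window
(which might be a sitting stretch, whose gravity is deliberately off-axis)
would be wrong.  For the correlation variants gravity is estimated per
activity segment: garment sensors shift when the wearer sits, so one
whole-day gravity vector is wrong for some postures.  Estimates with mean
magnitude below 0.5 g are rejected as unreliable.

### Five correlation variants

For each activity, up to three instances of 1500–2000 samples (30–40 s at
50 Hz) are cut from the interior of diary entries, with a 0.5 s guard band
at entry edges so transition artefacts stay out.  Pearson's r is computed
per axis, per instance, under five cumulative variants: `original`,
`time_aligned` (global lag removed), `rotated` (gravity-aligned only),
`aligned_rotated`, and `aligned_rotated_activitywise` (the residual lag
re-estimated and removed within each segment).  Instances are summarised
as median and variance; the variance is the population form (divide by
$n$) by default, with the sample form available — the choice is documented
because dispersion across three instances differs visibly between the two.
Single-instance groups report the median only.  A Shapiro–Wilk normality
check (on a fixed-seed subsample of at most 5000 points) is logged as
advisory context for the correlation and never gates it — gating would
silently change outputs.

The headline coefficient surfaced in summaries is the y-axis r: every
other stage of the pipeline privileges the gravity axis, and x/z carry the
heading ambiguity noted above.  All three axes are always computed and
written.

### Threshold decision-tree classification

Two features, both from the gravity-aligned y-axis: the acceleration
itself (posture: ≈ 1 g upright, ≈ 0 g with the thigh horizontal) and its
moving variance over a 250 ms centred window (movement and transition
intensity; short enough to catch brief transitions).  250 ms at 50 Hz is
12.5 samples; halves round *up*, giving an odd 13-sample window that
centres cleanly.  Edges use the truncated available window so the feature
has the same length as the signal.

The tree tests movement before posture:

| test | label |
|---|---|
| variance ≥ 0.05 g² | walking/running |
| variance ≥ 0.005 g² | transition |
| else, y ≥ 0.7 g | standing |
| else, y ≤ 0.5 g | sitting |
| else | transition (ambiguous static posture) |

The split order is a design decision: variance separates moving from
static unambiguously, after which the y-level reading is only trusted for
static samples.  Walking and running are one class; separating them is a
job for a richer classifier.  Labels are per-sample with no temporal
smoothing — smoothing exists as an off-by-default option only, so reported
agreement reflects the raw classifier.

The default thresholds are derived from the physics of the features
(upright ≈ 1 g, seated ≈ 0 g, sensor noise variance well below
0.005 g², gait variance well above 0.05 g²) rather than fitted; they are
config-overridable.  `estimate_thresholds(method = "quantile")` offers a
data-driven surrogate — variance splits at the 50th/90th percentiles of
the moving variance, posture splits at one third and two thirds of the gap
between the two dominant modes of the low-variance y histogram.  That
heuristic presumes a wear day that is roughly half static and about a
tenth gait, with intermediate variance in between; on days violating this
composition (for example gait-heavy lab protocols) its percentiles land
inside clusters rather than in the gaps between them, and the fixed
defaults are preferable.  A unimodal y histogram triggers an explicit
fallback to the defaults with a warning.

Agreement between the channels is a 4 × 4 confusion matrix with the
body-worn labels as rows (reference) and clothing labels as columns,
row-normalised to percentages; all-zero rows are reported as NA rather
than silently renormalised.

## The synthetic generator

`generate_body_stream` + `apply_clothing_transform` produce paired streams
with exactly the structure the pipeline assumes, so every stage is
testable without recorded data:

* **Postures.** Standing: gravity on +y (ay ≡ 1 g in the noise-free
  case).  Sitting: the thigh rotates, so gravity moves to +z and ay ≈ 0.
  Posture baselines ramp linearly over 0.5 s at boundaries (implemented as
  a boxcar smoothing of the step profile), producing the sudden
  moving-variance rise the classifier keys on while staying band-limited.
* **Gait.** A two-harmonic waveform per step — fundamental at the step
  frequency (2 / stride period: strides of 0.7 s walking, 0.3 s running)
  plus a half-amplitude second harmonic — giving the double-peak-per-stride
  morphology of real thigh data.  Peak amplitude defaults: 0.5 g walking,
  1.0 g running, applied fully on y and attenuated (0.5×, 0.3×) with phase
  offsets on x and z.  These are choices of plausible magnitude, not
  calibrated values.
* **Clothing channel.** In order: integer sample delay (edge padded by
  repeating the first sample, so lengths stay equal for paired analysis —
  lag tests exclude the padded edge), amplitude scaling (> 1 emulates the
  sharper garment peaks), a fixed rotation offset, additive fabric swing as
  a slow sinusoid on the anterior-posterior (x) axis only (garment swing is
  pendulum-like, predominantly along the direction of travel), and white
  Gaussian noise.  Negative lags (garment leading) are accepted so
  simulations can cover a symmetric lag range.
* **Markers.** A biphasic ≥ 4 g jump spike 0.5 s in, four 3.5 g taps at
  0.5 s spacing, and a closing jump written 10% larger so the
  end-of-recording marker is unambiguously the global magnitude maximum.

With a fixed seed, generation is exactly reproducible, and with zero noise
and swing the clothing transform is invertible away from the padded edge —
both properties are exercised in the test suite.

What the generator does **not** emulate: biomechanically realistic gait
(no stance/swing asymmetry, no step-to-step variability), cloth physics
(swing is a fixed sinusoid, not driven by the movement), sensor
nonlinearity or clock drift, and multi-day wear.  Passing tests therefore
demonstrate that the *algorithms* recover what they are designed to
recover under the assumed signal structure; they do not certify
performance on recorded garment data, where correlations are lower and
activity-dependent in ways a fixed swing term cannot reproduce.  The swing
parameters in particular are free knobs, not calibrated against any
garment.

## Validation scale and reproducibility

The validation suite and the acceptance script run the full pipeline on
problem sizes chosen to keep a desk run fast while leaving the statistics
meaningful: 200 seeded 30 s pairs for lag recovery across lags in
[−50, 50] samples; 20 trials for rotation recovery across 5–45°; 1000
random unit-vector pairs for rotation-matrix exactness; a 270 s
five-segment day for the end-to-end classification agreement.  Every
random draw flows from one configured seed, and a rerun with the same
configuration reproduces the run report byte for byte (the report JSON is
serialised with fixed settings for exactly this reason).

## Known limitations

* Integer-sample lag only; sub-sample (interpolated) lag estimation and
  time-varying lag (clock drift) are out of scope — the end jump is
  reported for drift inspection, not used for correction.
* Heading about gravity is uncorrected (accelerometer-only), capping
  x/z correlations.
* The classifier is deliberately minimal: four classes, two features,
  fixed thresholds; it is the agreement instrument, not a state-of-the-art
  activity recogniser.
* Reported correlations and confusion percentages on synthetic data are
  upper bounds on what recorded garment data would show.
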