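---
title: "Wavefront kinematics and classification of interictal events: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefront kinematics and classification of interictal events: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ictalwave)
```

## Scope and model of the data

`ictalwave` analyses voltage-sensitive dye (VSD) movies of spontaneous
interictal epileptiform events in horizontal hippocampal–neocortical slices,
together with concurrently recorded local field potentials (LFP).  A VSD
movie is a 200 Hz stack of 16-bit fluorescence frames; a fractional
fluorescence change (ΔF/F, on the order of 0.1%) is the proxy for population
depolarisation.  The analysis recovers, for each event:

* a per-pixel **onset (isochrone) map**: the time of the first positive
  crossing of a detection threshold set 2 SD above baseline activity,
  linearly interpolated between the bracketing frames;
* **propagation velocities**: inverse slopes of robust fits of onset time
  against distance along 1-D anatomical axis paths;
* **conduction times** between regions (earliest-onset differences);
* **saltatory jumps**: discontinuous spread where activity lands at a distal
  locus and back-fills toward the origin;
* an **event type**: hippocampal non-propagating (Type 1), neocortical
  non-propagating (Type 2), hippocampally originating propagating events
  without (3a) or with (3b) a reverberative return wave, or `unclassified`
  (e.g. events arising in medial entorhinal cortex);
* **LFP waveform morphology**: biphasic (two crossings of the mean + 2 SD
  level) versus triphasic (four crossings), the first-to-last crossing span,
  peak-to-peak amplitude, and interlaminar delays from paired recordings.

Every quantitative stage is validated by parameter recovery against a
synthetic-data generator whose events carry exact analytic onset times.

## The synthetic generator as the test bed

The generator (`simulate_event()`, `simulate_cohort()`, `simulate_lfp()`)
emulates the event taxonomy on a schematic slice atlas.  Its defaults *are*
the study conditions; they are chosen once and the tests and acceptance
analyses are run against them.

**Atlas geometry.** The default atlas (`default_atlas_config()`) is a
100 × 440 px grid at 25 µm/px (2.5 mm × 11 mm), with CA3 (0.5 mm), CA1
(2 mm), subiculum (0.5 mm), mEC (3 mm), lEC (3 mm), perirhinal cortex
(0.5 mm) and Au1 (1.5 mm, split into superficial L2/3 and deep L5/6
laminae) laid out along the hippocampo-neocortical axis.  The geometry is
schematic, not a tracing: regions are rectangles and axis paths straight
polylines ("no compensation for curvature" is also the measurement
convention).  The mEC and lEC widths were set at 3 mm so that a 0.47 m/s
backfill limb lasts >6 ms — i.e. comfortably longer than the one-frame
(5 ms) distal lead that defines a detectable saltation; in a narrower
periallocortex the jump-and-backfill signature would be sub-frame and
undetectable at 200 Hz by construction.

**Kinematic presets** (`kinematic_presets()`): CA1 0.37 m/s (propagating) /
0.17 m/s (non-propagating, confined to 0.5 mm), CA3 0.04 m/s, backfill
0.47 m/s, perirhinal 0.02 m/s; CA1→deep-Au1 total delay 25 ms, Au1→CA1
return 74 ms, L2/3→L5 8 ms, L5/6→L2/3 17 ms; reverberation latencies
0.42–0.78 s.  Peak ΔF/F per region: 0.14% (Type 1 origin), 0.16% (3a),
0.12% (3b), decaying toward 0.08–0.12% distally.

**Waveform.** Each pixel is exactly at baseline until its analytic onset,
then rises exponentially (0–95% in 20 ms) and decays with a 0.9 s
half-decay.  The half-decay was set so that the neocortical depolarisation
has *not* fallen to half its maximum anywhere in the admissible
reverberation-latency window (at the 0.78 s extreme the residual is 0.55 of
peak); with a substantially faster decay the reverberation criterion would
contradict the latency range it is meant to accept.

**Noise model.** Additive white Gaussian noise of 6.4 counts per pixel per
frame (20% of the largest default peak signal on a 20 000-count baseline)
plus a multiplicative 1%/s exponential bleaching trend.  Cohort events also
jitter their origin time uniformly within one frame: real events are
asynchronous to the camera clock, and this sub-frame phase variability is
load-bearing for averaged wavefront profiles (below).

**What the generator does not emulate**: shot-noise scaling with intensity,
spatially correlated (vascular/illumination) noise, slice curvature, motion,
partial dye loading, and wavefronts with internal structure (the full region
masks activate, rather than a band such as mid stratum radiatum).  Passing
the recovery tests therefore demonstrates correctness of the measurement
chain under idealised optics, not robustness to every artefact of real
recordings.

**Pial LFP traces** are sharp-spike + slow-wave composites on a 30 s epoch:
a biphasic event is a sharp negative spike followed by a slow positive
wave, a triphasic event a positive spike, a trough, and a slow wave
(spike-and-wave-like).  Because the +2 SD detection level depends on the
trace itself, the generator calibrates the slow-wave duration and the gain
by root-finding *through the same measurement chain used downstream*
(band-pass, then crossing span / peak-to-peak), so the default traces
realise the target span (1.17 s / 1.62 s) and amplitude (42 / 46 µV) by
construction.  Pial traces carry only 0.5 µV of noise — they stand for
event-averaged recordings.  Laminar pairs are larger (200 µV) sharp
discharges so that millisecond onset differences are physically resolvable.

## The conditioning chain

`preprocess_movie()` applies, in order: background subtraction (per-pixel
baseline-window mean), linear detrending (per-pixel line fitted on the
baseline window and extrapolated — first-order bleach removal), 2×2 spatial
binning (block means), and Savitzky–Golay differentiation.  Percent ΔF/F
conversion lives on the un-differentiated branch and is detrended the same
way.  Defaults: baseline window = first 0.5 s of the epoch (half-open, 100
frames at 200 Hz); SG window 11 frames (55 ms), order 3, first derivative in
units/s — wide enough to suppress frame noise yet an order of magnitude
shorter than the event rise.  SG coefficients come from `signal::sgolay`,
with off-centre projection rows at the movie edges; correctness is pinned by
analytic oracles (exact on polynomials up to the fit order, <1% against the
derivative of a 2 Hz sinusoid).  Because block means commute with the
per-pixel linear operations, the implementation bins first; the result is
identical and four times cheaper.

## Onset detection: design decisions

`compute_threshold_map()` is exactly the per-pixel baseline mean + 2 SD.
Around that definition sit three decisions that the zero-noise and
noise-robustness requirements force:

1. **Which signal is thresholded.**  The differentiated branch is
   implemented and selectable (`detect_on = "derivative"`), but the default
   detection branch is ΔF/F.  The centred 11-frame SG window is non-causal:
   a rise at `t` produces positive derivative estimates from `t − 25 ms`
   onward, and in the noiseless limit (where 2 SD → 0) the first positive
   sample — not the wavefront — sets the crossing, with the interpolation
   degenerating to frame quantisation.  On the ΔF branch the signal is
   identically baseline before onset, so the crossing is sub-frame exact.
2. **A relative floor for the level.**  The effective crossing level is
   `max(threshold_map, min_rise_frac × pixel peak)` with
   `min_rise_frac = 0.2`.  In the noiseless limit this keeps the crossing on
   the rising phase (interpolable, amplitude-independent timing); with noise
   it rides at or just above the 2 SD level.
3. **Debounce and spatial cleanup.**  A crossing must stay above level for
   5 consecutive frames, and `clean_onset_map()` removes pixels whose onset
   deviates from their 5×5-neighbourhood median by more than 4 ms (or that
   are spatially isolated).  With a 2 SD level, ~2.3% of pixels would
   otherwise ride a marginal pre-onset noise frame and report onsets one
   frame early; these artefacts are isolated in space while true wavefronts
   are locally coherent, which is exactly the contrast the cleanup tests.
   4 ms sits above onset jitter (~1 ms) and true within-neighbourhood
   gradients (≤2.5 ms even in the slowest, perirhinal, segment) and below
   the 5 ms one-frame error.

Sub-frame interpolation is linear between the bracketing frames; it is what
makes 8 ms laminar delays measurable on 5 ms frames.

## Velocities, saltations, reverberation

**Velocity** is the inverse slope of a Theil–Sen (median of pairwise
slopes) fit of onset against axis distance; OLS is available by
configuration.  The capture corridor (default 0.2 mm) takes the *earliest*
onset near each axis sample — an extreme statistic, so profiles inherit a
small uniform early bias that cancels in slopes.  Two residual artefacts
matter on short segments: corridor-edge flattening (within half a corridor
width of a segment end the corridor looks across the boundary), and the
frame-phase "sawtooth" of linear interpolation on a convex rise (up to
±0.7 ms, spatially coherent within one event because all pixels share the
frame clock).  Velocity recovery therefore measures slopes of
**across-event mean profiles** (`mean_axis_profile()`) with the fit
restricted to the segment interior (half a corridor width plus one binned
pixel inside each end).  Averaging over events with stratified sub-frame
origin phases cancels the sawtooth — the direct analogue of measuring the
slope of a mean wavefront over several slices.  Single-event Theil–Sen fits
remain exact (<2%) on clean profiles and are what the per-event tables
report.

**Saltation** detection works on the median-smoothed axis profile: a jump
is declared when a distal sample's onset precedes a proximal sample's by at
least `min_lead_s` (default one frame, 5 ms) across at least `min_jump_mm`
(default 0.2 mm); qualifying pairs are clustered by landing locus and the
backfill velocity is fitted (Theil–Sen, raw onsets) over the
back-propagating limb only.  On the default Type 3a kinematics this yields
the two periallocortical jumps (distal mEC, distal lEC) plus the
discontinuous arrival in Au1.

**Reverberation** cannot be a literal second crossing of the baseline
threshold: after the first discharge the fluorescence has not returned to
baseline (that is the half-max observation itself).  A second activation is
instead a rise of at least the pixel's detection increment above the
running post-onset minimum of its ΔF trace.  Re-entry is accepted when a
coherent population (≥5% of first-activated CA1 pixels, after spatial
cleanup) re-activates with latency inside `[0.3, 1.0]` s of the first Au1
onset — deliberately wider than the observed 0.42–0.78 s so the observed
extremes are measured, not hard-coded — *and* the Au1 region-mean ΔF,
sampled just before the return wave departs Au1, still exceeds half its
initial event maximum.  The early-side sampling keeps Au1's own
re-activation from vacuously satisfying the criterion.  Latency and the
74 ms return conduction use a robust earliest (5th percentile) of the
cleaned second-onset times.

## Classification

`classify_event()` is a pure decision table over origin region, recruited
regions (≥10% of a region's pixels with finite onsets — the colormap
figures quantify no fraction, so this is a configurable invention) and the
reverberation flag.  Events whose origin lies outside hippocampus and Au1,
or whose recruitment pattern fits no rule (e.g. hippocampal origin reaching
only the subiculum), are `unclassified` rather than forced — mirroring the
two observed mEC-origin events, which the default cohort includes.  On the
seeded default cohort the classifier is exact at zero noise and ≥95%
accurate at the default noise level.

## LFP morphology

Traces are conditioned with a zero-phase (forward–backward) Butterworth
cascade: 1st-order high-pass at 0.5 Hz and 3rd-order low-pass at 100 Hz.
The gentle high-pass order mirrors analog acquisition filters: a
forward-backward 3rd-order high-pass at 0.5 Hz annihilates the sub-hertz
body of a >1 s interictal slow wave, making the published crossing spans
unrealisable for any waveform; both orders are configurable.  Crossings of
the mean + 2 SD level (both moments over the whole analysis epoch; a
baseline-only mode is available) are counted with a 0.5 SD Schmitt-trigger
hysteresis so that noise chatter at the level cannot inflate the count, and
each retained crossing is reported at its interpolated level-crossing time.
"Line length" is implemented as the first-to-last crossing span in seconds
— the units force the duration reading; the classical sum-of-absolute-
differences EEG feature is a different quantity and is deliberately not
what this measure computes.  Initial polarity is the sign of the first
deflection exceeding 1 SD.  Interlaminar delay is the difference of the
channels' own first +2 SD crossings, in ms, signed by argument order.

## Numerical and degenerate-input conventions

* Coordinates are 0-based `(row, col)`, row 0 at top; `x = col·pitch`,
  `y = row·pitch`; frame `k` is at `k / frame_rate` seconds; windows are
  half-open `[start, end)`.
* Onset-map CSVs use `NA` for never-active pixels; movies and atlas label
  images are 16-bit grayscale multi-page TIFF with JSON sidecars (the only
  lossless representation available for floating-point-with-NA maps in the
  supported TIFF writer is none, hence CSV).
* Ties at the origin (onsets within one frame of the minimum) resolve to
  the pixel nearest the centroid of the near-minimal set.
* A flat profile yields an infinite-velocity flag, not an error; fewer than
  4 finite samples is an error.
* All randomness flows through explicit integer seeds; cohorts derive
  per-event seeds from the master seed, and identical configuration + seed
  reproduce every output byte-for-byte.

## Problem sizes used in the validation suite

The packaged tests and the acceptance analysis run the default-geometry
generator end to end: single events of 280–500 frames × 100 × 440 px, the
full 57-event cohort at zero and default noise, velocity-recovery ensembles
of 4–20 events with stratified origin phases, and 30 s LFP epochs at 2 kHz.
These sizes were chosen as the smallest at which each recovered quantity is
statistically stable against its published band; all scale linearly in
pixels × frames.

## Known limitations

* Velocities are measured along straight axis polylines; curved structures
  are systematically under-measured (by design, matching the measurement
  convention the kinematic presets correspond to).
* Onset phase coherence within a single event means single-event velocity
  estimates on segments shorter than ~1 mm carry a frame-grid bias; use
  across-event means there.
* The recruitment fraction (10%) and saltation thresholds are operational
  definitions, not biologically derived quantities.
* The classifier assumes one event per movie epoch; multi-event epochs must
  be segmented upstream.
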