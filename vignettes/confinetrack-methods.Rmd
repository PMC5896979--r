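---
title: "Methods: automated analysis of confined nuclear migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated analysis of confined nuclear migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(confinetrack)
```

`confinetrack` turns a multi-channel time-lapse stack of cells migrating
through a pillared microfluidic device into event tables: constriction
transits with their durations and outcomes, nuclear envelope (NE) rupture
events with their repair times, and cell divisions. This vignette explains
the model behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic validation data does and does not
emulate, and the design decisions that were genuinely open.

## Pipeline model

The pipeline assumes a device of horizontal rows of round pillars; the gap
between adjacent pillars is a constriction narrower than the nuclear
cross-section. Migration is directed (default: toward decreasing image y;
`migration_direction = "down"` mirrors every rule). Three channels are
expected: transmitted light showing the device, a chromatin marker (H2B
fusion) marking nuclei, and a nucleoplasmic reporter (NLS fusion) that
leaks into the cytoplasm during NE rupture.

### Device registration

Pillars are round, so an accumulator-based circular Hough transform over a
radius interval finds them: gradient-magnitude edge pixels vote for
candidate centres at each radius, accumulator peaks above a sensitivity
threshold become circles, and duplicate detections of one pillar at
neighbouring radii are suppressed keeping the stronger peak. Pillar centres
are clustered into rows (a gap in sorted y exceeding one pillar diameter
starts a new row — an invented but robust rule, since within-row centre
spacing is far tighter than row spacing for any plausible mounting angle),
each row is fitted with a line, and the weighted-mean slope gives the
correcting rotation, applied once, from the first frame, to the whole stack
with bilinear interpolation (background filled with the per-channel
median). Virtual entry and exit boundaries are drawn at centerline
± `boundary_offset_um`.

* `hough_radius_px` (default 6–14 px): a pillar's radius in pixels depends
  on magnification and camera, so no universal value exists; the default
  brackets the bundled synthetic device, and real data should set it from
  the known pillar size and pixel calibration.
* `hough_sensitivity` (0.5): fraction of an ideal full-circle accumulator
  peak; rendered pillars score ≈ 0.95 and clutter ≈ 0.25, so 0.5 separates
  them with wide margin.
* `boundary_offset_um` (7 µm): the calibration at which automated transit
  calls agree best with expert manual scoring; kept as the fixed default
  rather than re-derived, since the manual annotations needed to re-derive
  it are not distributable.

### Stabilization

Stage drift between consecutive frames is estimated on the transmitted
channel — its content, the device, is stationary by construction — by
normalized cross-correlation at integer lags: an FFT cross-correlation
proposes the lag, exact Pearson correlation over the overlap region refines
it in a ±3 window. Offsets are chained to frame 1 and every channel of a
frame is translated by the same amount. Sub-pixel registration is
deliberately not attempted: segmentation and event logic operate at pixel
resolution, and integer shifts keep intensity values unresampled.
`max_drift_px` (20) clamps implausible per-frame estimates with a warning.

### Segmentation

The nuclear channel is smoothed with a Gaussian of σ = 2.5 px. The
smoothing kernel's effective support matches a 10 × 10 px window; it is
implemented as a symmetric odd-sized kernel because a literal even-sized
10-tap kernel would translate the image by half a pixel and bias every
centroid. Foreground is every pixel above its local window mean
(`threshold_window_px` = 51) plus an offset of 20% of the dynamic range
(`threshold_offset_frac`). The offset fraction was calibrated so that
segmented masks stay tight around the true nucleus (intersection-over-union
with the generating ellipse >= 0.7): after sigma 2.5 smoothing, a small
offset places the mask boundary far down the blurred edge and dilates every
object by ~3 px, biasing bounding boxes and admitting speckles. When run
through `run_pipeline()` the range is taken over the whole sequence with
robust 0.1%/99.9% quantiles, because a frame that happens to contain no
cell has a noise-only range and a per-frame fraction of it would dissolve
into speckles. Holes
(chromatin texture) are filled before the distance transform.

Touching nuclei merge into one component; since nuclei are oval, the
Euclidean distance transform has one dome per nucleus and a watershed cuts
along the saddle. Minima shallower than `h_depth` (2 px of
distance-transform height) are suppressed first — the h-minima step —
preventing boundary roughness from over-segmenting. This is EBImage's
`watershed(distmap(mask), tolerance = h_depth)`, whose tolerance implements
exactly that suppression; increasing `h_depth` never increases the label
count. A nucleus squeezing through a pore takes a dumbbell shape that the
watershed would split in two, so any split whose parent component spans a
row's boundary band near a constriction midpoint is undone. Objects outside
30–600 µm² (`min_area_um2`, `max_area_um2`) or with circularity 4πA/P²
below 0.3 are discarded — except that in-constriction objects are exempt
from the circularity test, because a deforming nucleus is legitimately
non-circular. These cutoffs are calibrated to the synthetic nuclei (ellipse
axes 9 × 7 px at 0.8 µm/px ≈ 127 µm²), not taken from any published values.

Mean intensities are always measured on the **raw** channels over the final
label masks: measuring on smoothed images would make the rupture ratio
depend on blur radius.

### Tracking

Consecutive-frame observations are linked by the error function

E = d² + w_I·|ΔI| + w_A·|ΔA|,  w_I = w_A = 2,

with d the centroid displacement in px, I the mean chromatin-marker
intensity and A the area in px². The units are deliberately mixed — the
formula is reproduced as printed rather than dimensionally homogenised, and
the weights are exposed (`w_intensity`, `w_area`). Distance is computed in
px; the 40 µm gate (`max_distance_um`) is converted through the pixel size.
Candidate pairs within the gate are accepted greedily in ascending E, both
members leaving the pool; ties break lexicographically on (previous,
current) index. Linking is strictly frame-to-frame (no gap closing): a
nucleus missing for one frame ends its track and restarts as a new one.
This matches the sequential-greedy description of the original method; no
global assignment (Hungarian) is attempted, and the package's own test
oracle reproduces the greedy rule, not global optimality.

### Transit events

Per row, each observation is classified from its bounding box: *attempting*
if the leading edge has crossed the lower boundary while the trailing edge
has not cleared the upper boundary; *passed* once the trailing edge is
beyond the upper boundary; *outside* otherwise. A state machine per
(track, row) emits a success when an attempt reaches *passed*, a failure
when it returns *outside*, and an *ongoing* event when the movie ends
mid-attempt (excluded from transit-time statistics). Attempts whose
attempting streak is exactly one time point are discarded — cells sliding
parallel to a row graze the band for single frames. The discard is applied
unconditionally, including to a hypothetical one-frame success; the
scripted suites contain no such trajectory, and at realistic frame
intervals a full passage within one frame is not observable anyway.
Transit time is (exit − entry) × frame interval, with entry the first
attempting frame and exit the deciding frame — the endpoints are not
defined to the frame in the source description, so this is fixed here as
the package's convention; the 7 µm boundary calibration absorbed the same
ambiguity in the original. A failure immediately followed by a new attempt
is reported as two events with `adjacent_to_previous = TRUE`, leaving the
"one long attempt vs. two short ones" judgement to the analyst.

### NE rupture and mitosis

For each track the ratio r_t = mean chromatin marker / mean reporter is
formed per frame; because both channels bleach together, r is invariant to
photobleaching and global illumination changes (a property the test suite
checks exactly). Rupture starts when Δr_t > `jump_frac` (0.20) × r_{t−1},
or when r rises over at least `rise_len` (5) consecutive time points, the
start being the first frame of the monotone run. A step counts toward a
rise only if it gains ≥ `min_rise_frac` (0.01) of the previous ratio. This
floor deserves explanation: applied to continuous-valued ratios, a
rank-only "strictly increasing" rule fires on any flat noisy trace
(an ascending run of 5 values has probability 1/120 per window) and lets
runs of noise upticks leading into a jump drag the start frame early. Real
camera data is integer-quantized, where a strict increase means every step
gained at least one quantum — the per-step floor is the continuous analog.
Setting it to 0 restores the literal rank rule. Overlapping triggers merge
into one event at the earlier frame.

The event ends at the first frame after the ratio has departed more than
`baseline_tol_frac` (0.10) above its pre-rupture baseline at which it is
back within that tolerance and the frame-to-frame change has settled
(|Δr| ≤ `delta_zero_tol` (0.05) × baseline). A trace that never recovers
stays open and is excluded from duration statistics. Both tolerances are
numbers the source describes only as "close to its pre-rupture value" and
"returns to zero"; they are config-exposed.

NE breakdown at mitosis looks identical at onset, so a candidate rupture is
reclassified as a division when a new track begins within `mitosis_window`
(1 frame) of the start, its first centroid within `vicinity_um` (40 µm —
reusing the tracking gate) of the candidate nucleus. Single-frame ratio
spikes that immediately return still count as ruptures if the jump rule
fired. For population repair-kinetics curves, `normalize_rupture_trace()`
re-expresses each event's ratio relative to its value immediately before
rupture and scales the peak to 1.

## The synthetic generator

`render_scenario()` renders: dark soft-edged pillars on a bright
transmitted background; nuclei as anti-aliased ellipses (axes 9 × 7 px) or
as dumbbells (two lobes bridged through the pore) in the fluorescence
channels; a cytoplasmic halo of escaped reporter during scripted ruptures
(30% of the lost nuclear signal, kept outside the segmentation mask's reach
so the scripted nuclear means stay exact); global per-frame photobleaching;
integer stage drift; and i.i.d. Gaussian noise, all under a fixed seed
(bit-identical re-renders). Ground truth — per-frame identities and
positions, pillar centres, drift, and scripted transit/rupture/division
events — is emitted alongside, with event truth derived from the scripted
paths by an independent re-implementation of the boundary-crossing and
closure rules, not by the detector under test.

The fixed suites in `standard_suites()` define the validation conditions:
registration grids at rotations −5°…+5° with 12–24 pillars; a 50-frame
standard scene of 12 nuclei including a touching pair at 21 px (1.5 minor
axes — closer pairs are geometrically unsplittable at the default
`h_depth`, since their fused mask's saddle is shallower than 2 px) under
sawtooth drift and 0.3%/frame bleaching; 20 transit trajectories (2 × 10)
mixing successes with varying squeeze times, failures, one-frame grazes and
a parallel-motion graze; and 30 rupture traces with ratio jumps 10–60% and
exponential recoveries (τ = 1.5–10 frames, durations ≈ 3–18 frames), 10
divisions, and 10 flat controls at 2-min frame intervals. Fluorescence
background is low (0.005 vs. signal 0.5), emulating offset-subtracted
camera data; a large additive background would attenuate measured ratio
jumps below their scripted sizes.

What the generator does **not** emulate: optical point-spread blurring,
shot-noise statistics, autofluorescence texture, cells (cytoplasm) as
distinct from nuclei, out-of-focus drift, or segmentation-adversarial
chromatin texture. Passing the suites therefore demonstrates that the
event logic, tracking and geometry are correct and that the image
operators behave as designed on well-posed images — not that the default
segmentation parameters transfer to any particular microscope; on real
data the threshold, area and radius parameters should be reviewed against
a few frames first.

Scene sizes (≈ 520 × 360 px, 40–60 frames, ≤ 22 nuclei) were chosen so the
whole validation battery renders and analyzes in minutes on a single core
while still exercising every code path (empty frames, track births and
deaths, simultaneous events in all three rows).

## Numerical choices and degenerate inputs

* Pixel indices are 1-based (R convention), y increases downward; all
  boundary arithmetic is base-independent.
* Rotation uses inverse-mapped bilinear interpolation about the image
  centre; estimates are deterministic, so registration is reproducible
  bit-for-bit.
* Flat (zero-variance) frames: shift estimation warns and returns (0, 0);
  thresholding returns an empty mask; an empty device yields valid empty
  event tables.
* Zero reporter signal makes the ratio undefined; such frames are skipped
  with a warning.
* Ties in the greedy linker break on (previous, current) index order; ties
  in Hough non-maximum suppression break on accumulator score.
* CSV exports have fixed column order and `write.csv` formatting, so
  repeated runs on identical input are byte-identical.

## Known limitations

* No gap closing: a single missed detection splits a track, and a transit
  spanning the split is lost. The miss rate of the original automated
  analysis (8% vs. a 4-expert consensus) is of the same origin.
* The greedy linker can swap identities when two similar nuclei pass
  within the gate of each other between frames; the intensity and area
  terms mitigate but cannot exclude this.
* Rupture detection reads only the nuclear reporter mean; cytoplasmic
  signal, chromatin herniation and cell death are out of scope.
* The Hough stage assumes round pillars; other device geometries need a
  different registration front end, after which every downstream stage
  applies unchanged.
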