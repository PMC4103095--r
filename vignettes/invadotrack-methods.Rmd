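---
title: "Quantifying invadopodia-mediated ECM degradation: methods and design"
author: "invadotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying invadopodia-mediated ECM degradation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Invadopodia are actin-rich protrusions through which invasive cells locally
proteolyse the extracellular matrix (ECM).  In the fluorescent-gelatin
invasion assay, cells expressing an F-actin reporter (e.g. LifeAct-GFP) are
plated on a thin layer of dye-labeled gelatin and imaged in two channels
over many hours.  Candidate invadopodia appear as bright, compact actin
puncta in the marker channel; *functional* invadopodia additionally carve
dark holes into the ECM channel beneath them.  The package automates the
whole measurement chain for two acquisition regimes:

* **single-invadopodia mode** — high magnification (60×), one field per
  movie, a frame every 5 min for 12 h (144 frames), puncta-level output;
* **population mode** — low magnification (20×), many cells per field, a
  frame every 30 min for 25 h (50 frames), cell-level "degrader" output.

## Preprocessing

The correction chain runs in a fixed order: flat-field → registration →
photobleach → normalization.

**Flat-field.**  Every ECM frame (and, in population mode, every marker
frame) is divided by a unit-mean illumination profile.  When no acquired
reference is available the profile is estimated retrospectively as the
pixel-wise temporal median frame blurred with a Gaussian of scale 50 px
(configurable).  The median over time suppresses moving cells and
short-lived degradation; the wide blur keeps only the optical-scale
illumination pattern.

**Registration** (single mode only).  Stage drift is estimated per frame as
the integer translation maximizing FFT cross-correlation against the first
frame, searched within ±20 px.  The estimate is made on the ECM channel —
its static texture is the most stable landmark — and the same offset is
applied to both channels.  Vacated pixels are filled with the frame's
outside-cell mean.  Population movies are not registered.

**Photobleach correction.**  Frame *t* of the ECM stack is multiplied by
`s_t = mean(frame 1 outside cells) / mean(frame t outside cells)`.  Only
pixels *outside* the segmented cell bodies enter the estimate, so genuine
degradation (which happens under cells) cannot be absorbed into the bleach
model.  This per-frame ratio rescaling is exact and assumption-free; no
exponential fit is needed.

**Normalization** (single mode only).  A single global factor sets the
outside-cell ECM mean of the first frame to 1000, making local-difference
values comparable between gelatin preparations.  Population-mode metrics
are percentages and therefore scale-invariant, so normalization is skipped
there.

The cell masks required by the last two steps are segmented from the marker
channel.  When registration is enabled, provisional masks (from the
unregistered marker frames) supply the fill value and masks are re-segmented
afterwards — marker segmentation uses only relative intensities, so the
provisional masks are adequate for a fill estimate.

## Puncta segmentation

Per frame, on the raw marker image:

1. **High-pass filter**: the frame minus its Gaussian blur (default scale
   10 px, i.e. several puncta diameters).  This removes the diffuse cell
   body and leaves compact bright structure with zero-mean background.
2. **Frame statistics**: mean and population standard deviation of the
   filtered frame.
3. **Seeds**: 8-connected components of pixels above `mean + 3·sd`, keeping
   components of at least 6 px.  Both thresholds are the method's calibrated
   operating point and are configurable.
4. **Expansion**: each seed grows to the component of pixels above
   `mean + 1.75·sd` containing it; when two seeds share one expansion
   component, its pixels are split by nearest-seed distance (ties to the
   lower seed index) so regions stay disjoint.
5. **Shape filters**: inclusive area bounds (default 6–200 px) and
   major/minor axis-ratio bounds (default 1–4).  The axis ratio comes from
   the eigenvalues of the unweighted second-moment matrix of the pixel set;
   single-pixel-wide regions have a zero minor moment and are treated as
   ratio ∞, so they always fail a finite upper bound.  The default bounds
   stand in for the values a user would calibrate from manually annotated
   puncta, and should be recalibrated per cell line and marker.
6. **Cell restriction**: regions whose centroid falls outside the frame's
   cell mask are dropped — invadopodia are intracellular.

The cell mask itself is the marker frame blurred at 2 px, thresholded at
`mean + 1·sd` of the smoothed frame, hole-filled, with components under
50 px discarded.  This simple smooth–threshold–fill–filter strategy is a
replaceable component; any mask of the same shape can be supplied.

Because all thresholds are expressed in per-frame standard deviations,
segmentation is invariant to adding a constant to a frame and equivariant
under positive rescaling.  Raising the seed threshold strictly shrinks the
total retained seed area (the super-threshold masks are nested and the size
filter preserves subset relations), and raising the minimum seed size or
the expansion threshold strictly shrinks the count and the expanded area
respectively; the seed *count* versus the threshold is only a trend, since
an eroding component can momentarily split in two.  Whether statistics should be per frame or per
movie is genuinely open; per-frame is the default because it tolerates
slow focus and expression drift, and it is what the monotonicity and
recovery tests exercise.

## Tracking

Objects are linked frame to frame by pixel overlap: each region in frame
t+1 claims the frame-t region it shares the most pixels with (ties to the
lower track id); a region with several claimants keeps the largest-overlap
claimant and the others start new tracks; one shared pixel suffices; there
is no gap closing, so a one-frame disappearance ends a track.  Track ids
are deterministic, ordered by (start frame, min row, min col).  Lifetime is
frames present × frame interval, so 12 frames at 5 min equal the 1-h
single-mode filter and 20 frames at 30 min equal the 10-h population
filter; both filters are inclusive.

## Degradation measurement (single mode)

For every frame of a track, with the puncta's pixels as the *under* set and
the pixels within Euclidean distance 5 px of the region (minus the region,
minus any other segmented puncta) as the *border* set:

* local difference `L_t = mean(ECM over border) − mean(ECM over under)`;
* pre-birth difference `P_t`: the same frame-t pixel sets evaluated on the
  fixed ECM image immediately preceding the track's first frame (the first
  image, for tracks present from the start) — this captures pre-existing
  gelatin irregularities at the puncta's successive positions;
* corrected difference `C_t = L_t − P_t`, the degradation signal.

The "5-pixel border" is a Euclidean disk dilation; a Chebyshev (square)
ring differs only at the corners and was not worth a switch until someone
needs it.  Pixel sets move with the puncta; only the pre-birth *image* is
fixed.  Frames whose border is empty after exclusions yield missing values;
series with more than half their frames missing are flagged unusable and
never classified.

## Classification and properties

For each usable series the means of `L` and `C` are tested against zero
with classical two-sided one-sample t-tests.  p-values are Bonferroni
corrected for the number of tests in the experiment batch (2 per usable
series), and a track is called an invadopodium only when both corrected
p-values fall below α = 0.05 *and* both means are positive — the positivity
gate encodes the expected direction without changing the stated test.
Tracks with fewer than two usable frames or zero variance are never called.

Two statistical caveats are documented deliberately:

* **Batch scope.**  The Bonferroni batch is one analysis run.  Sensitivity
  of the classifier is therefore a per-experiment quantity: the package's
  power check classifies each simulated degrading series within its own
  experiment (m = 2).  Pooling hundreds of simulated series into one batch
  would measure the power of an unrealistically large correction, not of
  the method.
* **Shared baseline noise.**  `P_t` is estimated from a single image, so
  its noise becomes a small *constant* offset in every `C_t` of the track.
  For long-lived tracks the t-test can find that offset significant, which
  produces occasional false-positive calls on non-degrading puncta — the
  same residual false-positive behaviour the assay shows on MMP-inhibited
  controls, where flagged calls are reviewed manually.  The calls table
  keeps all the evidence (`mean_C`, both p-values) for such review.

Per classified invadopodium the package reports mean area (µm²), mean
distance from the nearest cell edge (µm, centroid to nearest boundary pixel
of its mask component), lifetime (min) and the time to maximum degradation:
the `C_t` series is smoothed with a centred 5-frame moving average (window
shrunk symmetrically at the ends; missing values linearly interpolated) and
the time from track start to the earliest frame reaching 90% of the
smoothed maximum is returned.  The 90% criterion is relative, so the
quantity is invariant to rescaling; it is undefined when the smoothed
maximum is not positive.

## Population mode

Cells are segmented with the same mask algorithm, taken as 8-connected
components, and filtered to 1,500–20,000 px (inclusive) to exclude debris
and unresolvable clusters; touching cells are not split — the upper size
bound removes them instead.  Tracks shorter than 10 h are discarded.

Degradation is quantified as background-corrected percentages.  With
`U`/`B` the mean ECM under the cell and in its 40-px border (excluding any
pixels occupied by a cell in the current *or* previous frame):

`D_t = 100 · ((U_prev − U_curr) − (B_prev − B_curr)) / B_curr`

Uniform bleaching or illumination changes hit `U` and `B` equally and
cancel.  The overall percentage `D_tot` applies the same formula to the
first and last frames, with the cell's *area of influence* — pixels covered
for at least 2.5 h cumulatively (inclusive) — as the under set and all
first/last-frame cell footprints excluded from its border.

Degrader cutoffs are calibrated on a negative control (an MMP-inhibited
condition in the lab; a no-degradation scene in simulation): the cutoff is
the smallest value such that at most `fp_budget` control cells exceed it
strictly — an order statistic, so with budget 0 the control maximum.  A
cell is a degrader when `D_tot` exceeds its cutoff *or* any `D_t` exceeds
the per-frame cutoff.  By construction the control itself yields zero
degrader calls; cells in an independent field whose statistics sit exactly
at the null can still exceed a zero-budget cutoff occasionally, which is
the known cost of calibrating to the extreme order statistic.

Degraded area compares first to last frame per pixel inside the influence
area: a pixel is degraded when it lost at least 20% of its initial
intensity (inclusive, per-pixel ratio — robust to spatial gelatin
heterogeneity).  The degradation rate is degraded area divided by the cell
lifetime in hours.

## The synthetic scene generator

`generate_scene()` renders both regimes with full ground truth so the whole
pipeline is testable without microscopy data.  Cells are soft-edged disks,
puncta are Gaussian spots on a jittered hexagonal lattice inside the cell;
degrading objects remove ECM intensity under their footprint at a constant
per-frame rate; the static ECM carries a smooth ±4% texture; the rendered
stacks then receive a multiplicative illumination gradient (±10%),
exponential photobleaching (half-life 240 frames) and additive Gaussian
noise.  Defaults: single mode, 256×256 px at 0.1075 µm/px, 144 frames at
5 min, one cell, 40 puncta (half degrading, footprint loss 4 units/frame on
a 2000-unit matrix, marker spot amplitude 150 over noise sd 15);
population mode, 520×696 px at 0.267 µm/px (the conversion implied by
1,500 px = 107 µm²), 50 frames at 30 min, 12 cells (one third degrading,
20 units/frame) plus short-lived debris blobs below the size filter.  The
field sizes are desk-scale choices: a 256² field holds one 60× cell with
40 resolvable puncta, and the population field is the native 20× camera
format.  Everything is deterministic under `rng_seed`.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: optical point-spread blurring and out-of-focus
light, Poisson (signal-dependent) camera noise, marker expression
heterogeneity, cell division and death, puncta motion within the cell, and
diffuse pericellular degradation halos.  Recovery results on these scenes
validate the measurement chain, not biological effect sizes.

## Numerical choices and degenerate inputs

* Connectivity is 8-connected everywhere (diagonally touching puncta are
  one object); components and track ids are ordered deterministically by
  (min row, min col).
* Dilation rings are exact Euclidean disks computed with a distance
  transform on a cropped window; results match exhaustive per-pixel scans
  bit for bit.
* A constant filtered frame (sd = 0) yields no seeds rather than an error;
  an all-background marker frame yields an empty cell mask; a frame whose
  mask covers everything makes photobleach correction fail loudly, naming
  the frame.
* Empty under/border sets propagate missing values, never silent zeros.
* Registration ties prefer zero shift; candidate shifts must beat the
  incumbent by a relative margin of 1e-9 to guard against floating-point
  ties in the correlation surface.
* The t-test refuses n < 2 or zero variance (`NA`, never called positive).
* The lifetime, size, coverage and degraded-drop thresholds are all
  inclusive at the boundary.

## Validation problem sizes

The test suite validates exact identities on random 48² stacks, brute-force
oracle agreement on one hundred 64² scenes, classifier calibration on 500
null and 200 degrading simulated series (n = 12), and end-to-end recovery
on the default single-mode scene (40 puncta) and a control/treated
population pair (12 cells each).  The same quantities are recomputed from
scratch by `scripts/acceptance.R`.

## Known limitations

* No gap closing in tracking: blinking puncta fragment into several tracks,
  each needing the lifetime filter on its own.
* Merged puncta and touching cells are not split (no watershed); population
  clusters are excluded by the size cap instead.
* The pre-birth baseline inherits single-image noise (see above).
* Translation-only registration; rotation or non-rigid drift is out of
  scope.
* The cell-edge algorithm is intentionally simple; masks from any external
  segmenter can be substituted wherever masks are accepted.
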