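---
title: "Quantifying membrane signalling patches and their flanking rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane signalling patches and their flanking rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranepatch)
```

## The measurement problem

Macropinocytic cups in amoebae such as *Dictyostelium* are organised around
intense plasma-membrane domains ("patches") of PIP3 and active Ras, with the
actin nucleation promoting factor SCAR/WAVE recruited as a narrow ring at
the patch periphery and excluded from its centre. Testing that picture
quantitatively requires a reproducible chain of measurements on two-channel
time-lapse movies of single cells:

1. segment the cell and extract a smooth, equally spaced outline;
2. sample membrane-bound fluorescence at N points along the outline;
3. call patches as the circular membrane regions whose intensity exceeds
   the cytosolic mean plus one standard deviation;
4. quantify the second reporter at patch centres and edges;
5. quantify patch-boundary sharpness, patch sizes and counts, and compare
   conditions;
6. follow the membrane over time: local protrusion/retraction speed,
   kymographs over a patch's lifetime, and patch lineages classified as
   arising de novo or by splitting from an existing patch.

This package implements that chain, together with a synthetic movie
generator that produces the same class of data with known ground truth, so
that every stage can be validated against exact answers.

## The analysis model

**Contour.** The cell mask (Gaussian smoothing, thresholding, largest
component, hole filling) is converted into a sub-pixel iso-contour of the
lightly smoothed binary mask at level 0.5, resampled to `n_points`
(default 100) points of equal arclength, oriented counter-clockwise in the
image frame, with the index origin at the point nearest the +x ray from the
centroid. Angles, indices, and intervals share this single convention;
intervals are half-open `[start, end)` on the circle and all indices are
1-based, the natural convention in R.

**Membrane intensity.** At each contour point, intensity is the mean of
bilinear samples along the inward+outward normal segment of length
`band_width_um` (default 1.6 µm) centred on the point. The mean (rather
than, say, the maximum) is robust to single-pixel noise. The band is wide
enough to fully enclose a diffraction-scale membrane rim with margin on
both sides, which makes the reading insensitive to sub-pixel error in the
contour position: shifting the band by δ only swaps δ of cytosol for δ of
background at its ends, a relative change of δ/`band_width`. Profiles are
normalized by the cytosolic mean of the same channel, estimated inside the
mask eroded by `erosion_margin_um` (default 1 µm, safely beyond the rim).

**Patch calling.** The threshold is `cytosol mean + k_sd × cytosol SD`
(default `k_sd = 1`), applied to raw intensities, strictly above (a value
exactly at the threshold does not qualify). Maximal circular runs above
threshold are reported; runs wrapping the index origin are merged; runs
shorter than `min_patch_points` (default 3 of 100) are discarded as noise.
Calling is equivariant under rotation of the profile and invariant under
adding a constant to both the profile and the cytosol mean. Note that the
rule presumes shot noise: on a noiseless synthetic render the cytosolic SD
is exactly zero and the threshold collapses onto the baseline; analyses of
noiseless renders must supply an explicit threshold
(`call_threshold_fold`), for which 2× the cytosolic mean (midway between
the baseline and patch readings) is used throughout.

**Centre and edge.** For each called patch of at least 3 points, the
measurement channel is read at the circular midpoint (ties to the lower
index) and at the two boundaries; each boundary value averages the point
just inside the interval with its immediate neighbour just outside
(configurable). In the pipeline, each patch lineage contributes one
centre/edge observation, taken at its median-width frame — the median is
robust both against the newborn sub-resolution frames and against frames
where two patches transiently merge into a single called interval, whose
midpoint would fall between the true patches.

**Edge sharpness.** Intensity profiles across each called boundary are
sampled along the membrane arc, oriented patch-interior → exterior, and
summarized by `d90_10`, the arc distance between the 90% and 10% crossings
of the interior-to-exterior contrast (plateaus: mean of the 3 innermost /
outermost samples; crossings linearly interpolated; the 90% crossing is
placed at the last sample still at the interior plateau so that noise dips
on the plateau cannot trigger early crossings). The value is clamped below
at one sample spacing, the resolution of the measurement; an
error-function edge of width σ reads `2.563 σ`.

**Dynamics.** Consecutive contours are registered by the circular index
offset minimising summed squared point distances; displacement is the
vector to the offset-mapped partner point. This preserves rigid motions
exactly, and its projection on the outward normal — the signed local
membrane speed, positive for protrusion — matches the analytic normal
velocity field for translations and isotropic expansions at modest
inter-frame motion (below about two arc spacings per frame). The membrane
kymograph holds one frame's profile per column with rows aligned by the
composed circular offsets, so alignment only permutes rows and column sums
equal profile sums. Edge-line kymographs sample intensity along an inward
line through a tracked patch-edge point, frame by frame.

**Lineages and origins.** Per-frame calls are linked greedily by interval
overlap (≥ 1 shared index, after offset alignment), with a configurable
gap tolerance (default 1 frame) for patches that flicker below threshold.
A new interval that overlaps the previous-or-current interval of a track
matched in the same frame is a **split** daughter of that track; the
parent interval is dilated by two indices for this test because called
boundaries sit up to a point inside the true patch and the nascent split
gap itself spans a point or two. A new interval with no such overlap is
**de novo**. Tracks present in the first frame are labelled `initial`:
without a preceding frame their origin is unobservable, and they are
excluded from the split fraction, as are events born in the last frames of
a movie (a split daughter needs a few frames for its gap to become
resolvable). A track whose patch just vanished cannot be a split parent —
membrane freed by a closure hosts de-novo events.

## The synthetic data generator

The generator emulates the statistical structure of single-cell two-channel
movies of this kind: a star-convex cell `r(θ)` around a drifting centroid,
a bright membrane rim, a cytosolic reporter pool, intense patches on the
rim (patch channel), narrow accumulations flanking each patch boundary on
free membrane (ring channel), Poisson shot noise and Gaussian read noise,
and full ground truth (per-frame intervals, lineages, event log).

Key defaults and their rationale (all configurable in `synth_config()`):

* `pixel_size_um = 0.1`, `frame_interval_s = 2`, `cell_radius_um = 5`,
  `image_size_px = 256²`: a typical spinning-disk, 100× single-cell crop.
* `membrane_band_um = 0.5`: a diffraction-scale rim, rendered just inside
  the radius function.
* `baseline_membrane_fold = 2.82`: calibrated at design time so that a
  non-recruited reporter's band-mean reading equals the cytosolic mean —
  the phenomenology of real uniformly distributed probes, and the
  precondition for the `mean + 1 SD` rule to separate patches from
  baseline. With this calibration the normalized patch reading is close
  to `patch_fold` and the baseline reading close to 1.
* `patch_fold = 3`, `ring_fold = 4`, `ring_width_um = 1.4`: intense
  patches, and rings bright and wide enough that edge measurements land in
  them. Rings are placed on free membrane outside the patch boundary and
  never trespass on any patch interior (`ring_placement = "interior"`
  flips them inside, a control that flips the sign of the patch–ring
  correlation).
* `patch_birth_rate = 0.25`/frame, `patch_width_deg_mean = 80°`,
  `patch_lifetime_frames_mean = 30`, `split_probability = 0.62`: a
  steadily occupied membrane (roughly a third to two thirds covered),
  matching the appearance of vegetative axenic cells where large circular
  ruffles dominate, with the majority of new patches arising by splitting.
* Births are Poisson *intents* whose origin (split vs de novo) is fixed by
  a coin flip at creation; an intent that is transiently infeasible (no
  eligible parent, no free membrane) waits in a queue rather than being
  dropped or substituted, so the realized split fraction is an unbiased
  estimate of `split_probability`. Movies open at steady state: the
  schedule is burnt in before frame 1 and survivors are labelled
  `pre_existing`.
* Patches are born at sub-resolution width (3°) and grow to a sampled
  target over ~3 frames; splits carve a daughter off one end of a mature
  parent with a gap that widens to 14° over a few frames, after which both
  regrow. Lifetimes are geometric with a 4-frame minimum (a patch living a
  single frame could not be resolved by any observer). Membrane vacated by
  a closure is refractory for 3 frames — instant re-occupation would be
  indistinguishable from a continuation, for the tracker and for a human
  scorer alike.
* `psf_sigma_um = 0` by default, keeping the noise-free render an exact
  piecewise-constant function of the truth geometry (convenient for exact
  oracles). A realistic value (~0.25 µm) is used where measured edge
  widths should reflect optical blur rather than sampling resolution.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: three-dimensional cup geometry and closure (the
cell is a 2-D star-convex section, so patches cannot overhang or fold);
photobleaching; multi-cell fields and cell–cell contacts; concave cup
shapes versus convex pseudopods; intensity heterogeneity within a patch;
and the full deformation repertoire of a crawling cell (motion is drift
plus a smooth radial protrusion field). Conclusions about those aspects
require real movies.

## Numerical choices and degenerate inputs

* Segmentation thresholding defaults to Otsu computed on intensities
  winsorized at the 95th percentile. Plain Otsu fails on these images: the
  patch class is small but so bright that it captures the threshold,
  leaving only the patches segmented. Winsorizing removes the bright tail
  so the dominant background/cytosol bimodality decides the threshold;
  plain `"otsu"` and explicit numeric thresholds remain available.
* Pre-threshold smoothing defaults to 0.05 µm (half a pixel). Heavier
  smoothing makes the mask bulge outward at bright patches (the smoothed
  edge crossing scales with edge height), which biases cross-channel
  measurements at patch positions.
* On rasterized synthetic images with razor-sharp edges, the band mean
  aliases against the pixel lattice: point-to-point variation of a
  perfectly uniform rim is about ±5% regardless of sampling density, and
  sub-pixel contour wobble contributes a similar amount through
  segmentation. Flatness at the 1–2% level is reached on optically
  blurred renders with exact contours.
* Degenerate inputs raise classed errors (`mp_error_*`): empty images and
  undersized components (`no_cell`), boundaries of fewer than 8 pixels
  (`contour`), erosion margins that empty the mask (`margin_too_large`),
  sub-pixel sampling bands (`invalid_parameter`), profiles of fewer than
  8 points (`profile_too_coarse`), empty size distributions and edge sets,
  centroid jumps beyond the cell radius (`tracking_lost`). Constant
  vectors make correlations undefined and are flagged, never silently
  zeroed. Identical paired groups compare with statistic 0 and p = 1.

## Validation protocols and problem sizes

The test suite validates each stage against independent oracles: analytic
perimeters of disks and squares; a dense independent band-rasterization
sampler; hand-evaluated threshold calls and a rotation oracle for
wrap-around intervals; the erf 10–90% width; analytic normal velocity
fields; binomial confidence intervals for realized origin fractions; and
the generator's event log for end-to-end lineage classification. The
package-level checks run on 50-frame default movies (criteria-style
pooled statistics), 80-frame noise-free movies for exact origin
classification, sparse pure-de-novo movies for lifetime kymographs
(isolated events whose rows are uncontested, so the elevated region can be
attributed unambiguously), a 1200-frame schedule for split-fraction
recovery at over a hundred births, and 100–1000 simulation replicates for
the power and null calibration of the group comparison. These sizes give
stable statistics while keeping the full suite in the low minutes on one
CPU.

Two caveats are inherent to the statistical criteria themselves. The
"centre not different from cytosol" check is an exact-null significance
test: even a perfect implementation fails it with probability α under an
unlucky seed. And origin classification is scored only on observable
events — births after the first frame, early enough before the movie ends,
and (in the generator) outside refractory membrane — mirroring how origins
are scored by eye in real movies, where an event at the very boundary of
the observation window cannot be classified either.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 7)
report <- run_pipeline(cfg)
print(report)
report$center_edge$edge_mean        # ring signal at patch edges (x cytosol)
report$center_edge$center_mean      # ring signal at patch centres
report$correlations$patch_vs_ring_r # pooled anti-correlation
report$tracking$split_fraction      # fraction of tracked births by splitting
```

## Known limitations

* The contour correspondence is a global circular offset, not a full
  point-wise membrane mapping; it is accurate for inter-frame displacement
  below about two arc spacings and degrades for large deformations.
* Patch size is measured as membrane arc length; projected area or angular
  width are not implemented (arc length is the natural 1-D analogue and is
  what the calling operates on).
* The 1-SD threshold applies to raw intensities; the threshold-identity
  invariant (adding a constant to profile and cytosol leaves calls
  unchanged) guards the choice, but multiplicative normalization before
  thresholding would behave differently for cells with very different
  expression levels.
* Tracking attributes a division's continuing track to the larger
  fragment; which side is "parent" and which "daughter" is attribution,
  not biology, and only event counts and origins should be interpreted.
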