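# membranepatch

Quantification of plasma-membrane signalling patches and their flanking
rings in two-channel time-lapse fluorescence movies of single cells.

Macropinocytic cups in amoebae are organised around intense membrane
domains ("patches") of PIP3 and active Ras; actin nucleators such as the
SCAR/WAVE complex are recruited as a narrow ring at the patch periphery and
excluded from its centre. This package implements the measurement chain
that makes those statements quantitative, plus a seeded synthetic-movie
generator with full ground truth so every stage can be validated against
known answers.

## What it computes

For a movie with a *patch* channel (e.g. a PIP3 reporter) and a *ring*
channel (e.g. a SCAR reporter):

- **Segmentation and contour** — cell mask (winsorized-Otsu threshold,
  largest component), sub-pixel outline resampled to N = 100 points of
  equal arclength.
- **Membrane profile** — at each contour point, the mean of bilinear
  samples along the normal over a band (default 1.6 µm), normalized to the
  cytosolic mean (interior of the eroded mask).
- **Patch calling** — maximal circular runs of points with raw intensity
  strictly greater than `cytosol mean + k·SD` (default k = 1), wrap-around
  merged, runs under 3 points discarded. A patch's size is its membrane
  arc length.
- **Centre/edge quantification** — the second channel at each patch's
  circular midpoint and at its two boundaries, in cytosol units; paired
  two-tailed t-tests against the cytosolic background.
- **Channel statistics** — pooled 2-D histograms and Pearson/Spearman
  correlations between channels (patch vs ring is strongly negative when
  rings flank patches) and between local membrane speed and intensity.
- **Edge sharpness** — intensity profiles across each patch boundary along
  the membrane; `d90_10`, the 10–90% contrast distance (an erf edge of
  width σ reads 2.563 σ).
- **Dynamics** — contour registration (circular offset), signed normal
  membrane speed (µm/s, positive outward), membrane kymographs aligned so
  a material point stays on one row, edge-line kymographs through a
  tracked patch flank, and patch lineages linked by interval overlap with
  each birth classified **de novo** or **split**.
- **Reporting** — a deterministic JSON report plus CSV/TIFF artifacts, and
  Welch comparisons of patch size/count/intensity between conditions with
  Holm correction.

The synthetic generator (`synth_config()`, `make_cell_movie()`) renders a
drifting, protruding star-convex cell with a bright membrane rim, patches
that are born (de novo or by splitting a parent), grow, and close, rings
flanking every patch boundary, and Poisson + Gaussian noise — with the full
schedule, lineage tree, and event log returned as ground truth.

## Worked example

```r
library(membranepatch)
report <- run_pipeline(pipeline_config(seed = 7))
print(report)
#> <pipeline_report>
#>   50 frames (0 failed), cytosol mean + 1*SD
#>   patches: 5.66 per frame, 283 sized (mean 3.83 um)
#>   centre/edge (n=14): edge 2.65 (p=1.09e-11), centre 0.999 (p=0.928) vs cytosol 1
#>   correlations: patch~ring r=-0.816, speed~ring r=0.0733
#>   tracking: 14 lineages, split fraction 0.429
```

Reading this: on a default 50-frame synthetic movie the pipeline called
5.7 patches per frame with a mean arc length of 3.8 µm; the ring channel at
patch **edges** averaged 2.65× the cytosolic background (overwhelmingly
significant, paired t-test) while at patch **centres** it was
indistinguishable from cytosol (0.999×, p = 0.93) — the centre/edge
dichotomy. Pooled over all membrane points, the patch and ring channels
anti-correlate (r = −0.82). Of the patch births observable in the movie,
43% arose by splitting an existing patch (this movie's realized value;
the generator's configured probability is 0.62 and converges over many
births).

A thin command-line wrapper over the same functions is installed at
`inst/cli/membranepatch.R` (subcommands `generate`, `run`, `compare`).

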