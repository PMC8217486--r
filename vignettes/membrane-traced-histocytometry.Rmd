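---
title: "Membrane-traced histo-cytometry: models, parameters and design"
author: "rrsfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-traced histo-cytometry: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsfish)
```

## The problem

Quantifying engineered T cells in tissue requires counting RNA FISH dots
*per cell*, and in dense tissue the cell boundary — not the nucleus — is the
limiting piece of information. Nucleus-seeded watershed segmentation fails
when cytoplasmic mRNA surrounds nuclei of tightly packed cells. `rrsfish`
instead segments cells from a plasma-membrane counterstain (wheat germ
agglutinin, WGA): bright membrane ridges are traced into closed loops, and
everything else — nuclei, FISH dots, immunohistochemistry (IHC) signal — is
detected independently and attributed to the loop that contains it. The
per-cell table that results is a flow-cytometry-style event list
(histo-cytometry): every row a cell with its global position, area, dot
counts per RNA channel and IHC intensity, ready for threshold gating.

## Membrane tracing as a hidden-Markov walk

Seeding and tracing work on one tile at a time:

1. **Seeding.** `n_seeds` positions (default 4000 per tile — several
   thousand) are drawn uniformly without replacement from masked pixels at
   or above the `seed_intensity_percentile` (default 80) of membrane
   intensity. Seeds on background die immediately (see the score floor), so
   over-seeding is cheap and under-seeding is the only real risk.
2. **Walks.** Each seed launches a walker whose state is a quantised
   heading (default 16 directions). Per step the walker considers turning
   by up to two direction quanta (±45°) and scores each candidate position
   as

   `score = intensity_weight * log(I / B) − turn_penalty * |Δθ|`,

   where `I` is the bilinearly interpolated membrane intensity at the
   candidate and `B` a local background (Gaussian blur of the membrane,
   sigma `bg_sigma_px` = 8 px). Emissions reward ridge contrast; transitions
   penalise turning; decoding is greedy per-step maximum likelihood. The
   walk stops when the best score drops to the floor (0: the candidate is no
   brighter than its surroundings), when it leaves the analysis mask, at
   `max_steps`, or when it has travelled at least `min_perimeter_px` and
   returned within `closure_radius_px` of its origin — a closed loop, i.e. a
   cell. A second walk in the opposite initial heading is concatenated when
   the first does not close.

   The turn penalty (0.3 per radian) and intensity weight (2.0) were
   calibrated once on noiseless circle phantoms: the penalty must be small
   enough that the walker pays for a quantised 22.5° turn whenever staying
   straight means drifting off a ridge of typical curvature (cell radius
   ≥ 8 px), and large enough to damp zig-zagging on noise. With the
   defaults, a circle of radius 20 px is traced with a perimeter error
   under 5%.
3. **Net draft.** Closed traces, and open traces whose mean per-step score
   clears `net_accept_loglik` (0.2), are rasterised (midpoints included so
   1.5 px steps leave no gaps), thickened by one pixel, and skeletonised
   (Zhang–Suen) to a one-pixel-wide net.

   One guard beyond trace acceptance proved necessary: net pixels must also
   sit on membrane intensity above the masked median plus 5 robust noise
   SDs (MADs). Without it, walks that meander across noisy background
   between sparsely placed cells build corridor walls; the regions they
   enclose are bounded entirely by net pixels, so a boundary-coverage test
   alone cannot reject them. The intensity support test removes such walls
   at the source and is part of what "removes false positive membranes".
4. **Loop extraction.** Connected background regions (4-connected, which an
   8-connected net curve separates correctly) that do not touch the image
   border become loop candidates. Candidates are rejected when their area
   leaves the configured bounds (derived from the accepted cell diameter
   range via the pixel size) or when less than `coverage_min` (0.8) of
   their boundary pixels are adjacent to net pixels. Loop area is the pixel
   count plus half the boundary (the membrane midline splits boundary
   ownership); polygons are traced counter-clockwise through
   boundary-pixel centres.

## Detection and attribution

Nuclei, FISH dots and IHC are detected on the scale-normalised negative
Laplacian-of-Gaussian response. Defaults: dot scale 0.6 µm / pixel size,
nucleus scale 3 µm / pixel size; minimum separation 2 px; prominence
threshold 5× the MAD of the masked response, floored at 2% of the peak
response so that numerically tiny ripple cannot pass on noise-free images,
and at the FFT round-off scale of the input. The LoG kernel is normalised
to zero sum so constant images give exactly zero response.

Dots are assigned to loops by the even-odd point-in-polygon rule with a
half-open convention; points on or up to 1.5 px outside a contour are
attributed to the nearest loop. The 1.5 px tolerance reflects geometry, not
tuning: the extracted contour runs through region boundary-pixel centres,
about one pixel *inside* the membrane ridge midline, and a dot lying under
the membrane band belongs to the cell on whose side it sits. Points inside
no loop are reported as unassigned, never attributed, so
`assigned + unassigned = detected` holds per channel.

IHC is summarised as the mean interior intensity (boundary pixels excluded)
minus the masked median of the channel. A diffuse stain has no meaningful
dot count; gating needs a single scalar per cell. A maxima-count readout
remains available by running `log_maxima()` on the IHC channel. The default
IHC positivity gate picks the threshold minimising intra-class variance
(Otsu) per section; when the criterion is flat across an empty gap between
classes, the middle of the flat plateau is used.

## Tiles, borders and vignetting

Mosaics are analysed tile by tile. A border strip (`border_px` per side) is
omitted from each tile to compensate acquisition overlap; the excluded
fraction is the exact ratio `1 − ((s − 2b)/s)²`, which for a 2048 px tile
with 48 px strips is 8.94% ≈ 9%. (The strip arithmetic `4bs/s²` double
counts the four corners; both round to 9% at these settings.) A loop whose
centroid falls in the strip is dropped from that tile — a deterministic
single-assignment rule for cells cut by tile edges. Tiles are assumed to
abut edge to edge; no intensity-based stitching is attempted.

Vignetting is modelled as a multiplicative Gaussian gain,
`gain = baseline + amplitude · exp(−d²/2σ²)`, fitted by least squares to a
16×16 grid of local medians (robust to cells riding on the illumination
field). Correction divides by the gain and rescales to preserve the image
mean; it is deliberately not idempotent. Fits with vanishing width,
negative amplitude, or a gain that collapses in the corners fall back to
the identity model with a warning — on structure-dense images such as the
honeycomb phantom this fallback is the expected and correct behaviour.

## The synthetic scene generator

The generator is the package's oracle: every test that claims recovery
compares against its exact ground truth.

What it emulates: convex cells (radial perturbation ≤ 20% of a base circle,
then a convex hull — roundish lymphocytes and tumour cells) placed by
rejection sampling without overlap (or abutting, for confluent-tissue
phantoms, including a perfect honeycomb lattice); membrane ridges with a
Gaussian cross-profile (width 2 px, contrast 120 over a base level 8);
1–2 nuclei blobs per cell; punctate FISH dots at per-phenotype Poisson
rates; diffuse IHC fill in tumour cells; a centred multiplicative Gaussian
vignette; Poisson shot noise plus Gaussian read noise. All randomness flows
from a single integer seed, and a fixed seed reproduces scenes and pixels
bit for bit.

Choices a user should know about, set once as study conditions:

* **Dot placement.** Dots are cytosolic: at least 1 µm inside the cell
  boundary, and at least 1.5 µm apart (RNAscope dots are
  diffraction-limited, separable objects; counting overlapping dots is
  deconvolution, which this package does not do). Both constraints relax
  gradually when a small cell cannot hold its drawn count, because count
  conservation — truth equals rendered centres — takes precedence.
* **Dot size.** Rendered dot sigma is 0.4 µm, the diffraction scale of a
  40× / high-NA system sampled at 0.5 µm pixels. Detection uses a slightly
  wider 0.6 µm scale, a standard robustness choice.
* **Dilution series.** The in-vitro validation design: marker-positive
  cells of purity 0.90 mixed at ratios 1, 0.75, 0.5, 0.25, 0 into negative
  cells, 1000 cells per point, 8–14 µm diameters, CAR dot rate 8 per
  positive cell vs 0.2 background, default noise. Expected positive
  fractions are 90%, 67.5%, 45%, 22.5%, 0%.
* **Density.** True tissue densities are a free parameter (they are not
  calibrated to any published section); scenes here target ≈ 20–25% areal
  packing.

What it does **not** emulate: autofluorescence structure, z-stacks (inputs
are assumed projected), point-spread functions beyond Gaussian blobs,
irregular or concave cell shapes, and segmentation-confounding debris.
Passing recovery tests on these scenes therefore demonstrates the
algorithms' correctness under controlled conditions, not performance on
arbitrary real tissue.

## The marker-high / marker-low partition

For spatial effector-gene analysis the section is split by tumour-marker
(CD19) expression: each marker-positive cell contributes a circle of its
equivalent radius `r = sqrt(area/π)` expanded 16-fold; cells whose expanded
circles overlap (centroid distance < sum of expanded radii — the mutual
overlap reading) form connective groups; the largest group's disc union,
clipped to the analysed tissue, is the marker-high area, the remainder the
marker-low area. "Largest" means most member cells, ties broken by larger
disc-union area — member count is robust to the area scale. Disc unions and
the tissue clip are computed analytically as polygon unions (64-gon discs);
a 1 µm rasterisation cross-check agrees within 1%. Cells are assigned to
the high region exactly (centroid within any member disc), so every cell is
assigned exactly once and `area_high + area_low = area_tissue` by
construction.

The analysed tissue area is the summed analysis-mask area of tiles that
contain at least one cell — the paper-facing quantity "per mm² of section"
needs a denominator and this one is explicit, deterministic and additive. A
convex hull of the cell centroids is available behind a flag as the
alternative (a concave hull would track ragged sections better, but no
installed dependency provides one and hull construction is not this
package's contribution).

Significance tests mirror the study design: a two-sided paired t test for
per-section high-vs-low comparisons and classical equal-variance one-way
ANOVA across phenotype groups. Degenerate inputs are explicit: zero
variance of the paired differences is an error; zero within-group variance
with distinct means yields an infinite F that is flagged, not hidden. No
multiple-testing correction is applied, and no post-hoc test is included.

## Problem sizes and numerical choices

The validation suite uses: 5 × 1000-cell dilution scenes on 2×2 mosaics of
768 px tiles; a 100-cell honeycomb (hex radius 7 µm) on one 320 px tile;
60-cell count-oracle scenes on one 520 px tile; 100 random partition
configurations of up to 500 cells. These sizes keep every recovery
statistic at a scale where its tolerance is meaningful (binomial SE ≈ 1.5
percentage points at n = 1000) while a full run stays in the minutes range
on a single core.

Other numerical choices: coordinates are 0-based with x along columns, y
along rows, origin at the tile's top-left pixel; 16-bit integer tiles
round-trip TIFF exactly, float tiles via 32-bit pages; ties in seed
sampling, maxima thinning and loop ordering are broken deterministically
(response descending, then lower (y, x)); child RNG streams are derived
from the master seed per tile and per scene, so mosaics are reproducible
independently of processing order.

## Known limitations

* The tracer is greedy (beam width 1); a Viterbi decoder over the heading
  chain could recover from locally misleading contrast at junction-rich
  membranes, at several times the cost.
* Deep-learning refinement of the segmentation is out of scope; the
  classical tracing path stands alone.
* Counts in cells whose dots genuinely overlap within the diffraction
  limit are undercounts; no cluster deconvolution is attempted.
* The vignette fit assumes a centred gain; off-centre vignetting falls
  back to identity rather than fitting the centre.
* Gating thresholds (≥ 3 dots for RNA positivity, Otsu for IHC) are
  defaults recorded in the table metadata, not biological constants; real
  analyses should set them per experiment.
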