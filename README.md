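# rrsfish

Membrane-traced histo-cytometry for RNA FISH tile scans.

`rrsfish` quantifies RNA FISH dots, nuclei and immunohistochemistry (IHC)
signal **per cell** in multichannel fluorescence mosaics of tissue sections
and cytospins — the analysis needed to track engineered cells (for example
anti-CD19 CAR T cells) and their effector-gene expression (*GZMB*, *IFNγ*)
relative to tumour cells in preclinical models. It is aimed at imaging
groups who stain with a wheat-germ-agglutinin (WGA) membrane counterstain
and want flow-cytometry-style per-cell event tables out of whole-section
tile scans.

## What it does

* **Cell segmentation from the membrane stain.** A random-reaction-seed
  (RRS) algorithm scatters thousands of seeds on bright membrane pixels and
  extends each by a hidden-Markov ridge walker: states are quantised
  headings, emissions reward local ridge contrast
  (`log(I / background)`), transitions penalise turning, decoding is
  greedy maximum likelihood. Walks that return to their origin close a
  loop — a cell. Accepted traces are rasterised and skeletonised into a
  net-like membrane draft; enclosed regions that pass area and
  boundary-coverage filters become cell loops (false membranes are
  discarded).
* **Detection.** Scale-normalised Laplacian-of-Gaussian local maxima for
  nuclei and FISH dots; mean interior intensity for diffuse IHC. Every
  detection is attributed to the loop that contains it
  (`assigned + unassigned = detected`, always).
* **Histo-cytometry table.** One row per cell — global x/y in µm, area,
  nuclei count, dots per RNA channel, IHC level — exported as the plain
  numeric CSV that flow-cytometry gating software ingests.
* **Mosaic handling.** Per-tile analysis with a configurable border strip
  excluded on each side (9% of a 2048 px tile at 48 px), Gaussian
  vignetting correction, exact tile-to-global coordinate mapping.
* **Spatial statistics.** Tissue partition into marker-high / marker-low
  areas by 16-fold circle expansion around marker-positive tumour cells and
  connective grouping; cell densities per mm² per region; paired t tests
  and one-way ANOVA.
* **Synthetic ground truth.** A first-class scene generator (membrane
  ridges, nuclei, Poisson-rate FISH dots, IHC fill, vignetting, noise) with
  exact per-cell truth — every recovery claim in the test suite is measured
  against it.

## Worked example

Generate a synthetic cytospin-like scene with known truth, image it, and
run the full pipeline:

```r
library(rrsfish)

gt <- generate_layout(
  120, c(256, 256), c(8, 14),
  phenotype_mix = c(car_pos = 0.4, car_neg = 0.6),
  phenotypes = list(phenotype_spec("car_pos", c(rna_1 = 8)),
                    phenotype_spec("car_neg", c(rna_1 = 0.2))),
  rng_seed = 17)

layout <- mosaic_layout(1, 1, side_px = 512, border_px = 32,
                        pixel_size_um = 0.5)
tiles  <- render_tiles(gt, optics_config(tile_side_px = 512, rng_seed = 4),
                       layout, channels = c("membrane", "nuclei", "rna_1"))

cells <- analyze_mosaic(tiles, layout, rna_names = c(rna_1 = "CAR"),
                        rng_seed = 6, cell_diameter_um = c(8, 14))
dplyr::select(cells, cell_id, x_um, y_um, area_um2, nuclei, CAR)
#> # A tibble: 93 × 6
#>   cell_id  x_um  y_um area_um2 nuclei   CAR
#>     <int> <dbl> <dbl>    <dbl>  <int> <int>
#> 1       1 120.   23.7     91.1      1     7
#> 2       2  34.5  26.9     87.9      1     1
#> 3       3  64.9  27.5    141.       1     5
#> 4       4 217.   28.5    100.       1     7
#> # ℹ 89 more rows
```

93 of the 120 true cells are reported — the rest have centroids in the
excluded 32 px border strip — and none are false loops
(`match_cells(cells, gt)`). Gating at the default ≥ 3 dots:

```r
gate_cells(cells, gate_spec("CAR+", "CAR", 3))
#> <gate_result> CAR+: 40 / 93 positive (43.01%)
```

against a true positive share of 40% in this scene. `export_cells_csv()`
writes the table for external gating;
`autoplot(cells, colour_by = "CAR")` maps the section. For spatial
analysis, `cd19_partition()` + `spatial_density()` split the section into
marker-high/low areas and compute per-mm² densities, with `paired_t()` and
`one_way_anova()` for the section-level comparisons.

A thin command-line front end over these functions lives at
`inst/cli/rrsfish.R` (`synth`, `analyze`, `spatial` subcommands).

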