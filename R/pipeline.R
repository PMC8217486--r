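# End-to-end per-tile analysis and mosaic assembly.

#' Analyse one tile: segmentation plus per-cell detection
#'
#' Runs the full per-tile chain: optional vignetting correction, reaction
#' seeding and ridge tracing on the membrane channel, net and loop
#' extraction, LoG detection of nuclei and FISH dots with per-cell
#' assignment, and IHC quantification.
#'
#' @param tile A [tile_image()] (must contain a `membrane` channel).
#' @param layout A [mosaic_layout()] (supplies the analysis mask).
#' @param rrs An [rrs_params()].
#' @param detect A [detect_params()].
#' @param cell_diameter_um Accepted cell diameter range; sets the loop area
#'   bounds via the pixel size.
#' @param coverage_min Loop boundary-coverage threshold.
#' @param vignette Correct vignetting before analysis?
#' @param rng_seed Integer seed (seed placement); derived per grid position
#'   so mosaics are order-independent.
#' @return A list: `loops`, `dots` (per RNA role: counts tibble),
#'   `nuclei` (counts tibble), `ihc`, `spots`, `grid_pos`,
#'   `n_unassigned` (per role).
#' @export
analyze_tile <- function(tile, layout, rrs = rrs_params(),
                         detect = detect_params(),
                         cell_diameter_um = c(5, 25),
                         coverage_min = 0.8, vignette = TRUE,
                         rng_seed = 1L) {
  stopifnot(inherits(tile, "tile_image"))
  if (!"membrane" %in% names(tile$channels)) abort("missing channel: membrane")
  pix <- tile$pixel_size_um
  if (vignette) tile <- correct_vignette(tile)
  am <- analysis_mask(layout)
  mask <- am$mask
  area_bounds <- c(0.5 * pi * (cell_diameter_um[1] / 2 / pix)^2,
                   1.6 * pi * (cell_diameter_um[2] / 2 / pix)^2)
  tile_seed <- derive_seed(rng_seed,
                           tile$grid_pos[1] * layout$n_cols + tile$grid_pos[2])
  seg <- rrs_segment(tile$channels$membrane, mask, rrs, area_bounds,
                     coverage_min, rng_seed = tile_seed)
  loops <- seg$loops

  rna_roles <- intersect(c("rna_1", "rna_2"), names(tile$channels))
  dots <- list(); n_unassigned <- list(); spots <- list()
  for (role in rna_roles) {
    ss <- log_maxima(tile$channels[[role]], detect$spot_sigma_px,
                     detect$min_prominence, detect$min_separation_px, mask)
    asg <- assign_points_to_cells(ss, loops)
    dots[[role]] <- asg$counts
    n_unassigned[[role]] <- asg$n_unassigned
    spots[[role]] <- ss
  }
  nuc <- if ("nuclei" %in% names(tile$channels)) {
    ns <- log_maxima(tile$channels$nuclei, detect$nucleus_sigma_px,
                     detect$min_prominence,
                     max(detect$min_separation_px, detect$nucleus_sigma_px),
                     mask)
    assign_points_to_cells(ns, loops)$counts
  } else {
    tibble(loop_id = loops$loop_id, n = NA_integer_)
  }
  ihc <- if ("ihc" %in% names(tile$channels)) {
    measure_ihc(tile$channels$ihc, loops, mask)
  }
  list(loops = loops, dots = dots, nuclei = nuc, ihc = ihc,
       spots = spots, grid_pos = tile$grid_pos,
       n_unassigned = n_unassigned)
}

#' Analyse a whole mosaic into a cell table
#'
#' @param tiles List of [tile_image()]s covering the layout.
#' @param layout A [mosaic_layout()].
#' @param rna_names Optional renaming of RNA roles to marker names.
#' @param ... Passed to [analyze_tile()].
#' @inheritParams analyze_tile
#' @return A `cell_table` (see [build_cell_table()]).
#' @export
analyze_mosaic <- function(tiles, layout, rna_names = NULL, rng_seed = 1L,
                           ...) {
  results <- map(tiles, analyze_tile, layout = layout, rng_seed = rng_seed,
                 ...)
  build_cell_table(results, layout, rna_names)
}
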