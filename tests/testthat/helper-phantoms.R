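# Shared synthetic phantoms built in code at test time.

# Noiseless circular membrane ridge: radius r_px, ridge width w_px,
# centred in a side x side image on background `base`.
ring_phantom <- function(side = 101, r_px = 20, w_px = 2, contrast = 120,
                         base = 8, cx = (side - 1) / 2, cy = (side - 1) / 2) {
  xg <- matrix(rep(0:(side - 1), each = side), side, side)
  yg <- matrix(rep(0:(side - 1), side), side, side)
  d <- sqrt((xg - cx)^2 + (yg - cy)^2)
  base + contrast * exp(-(d - r_px)^2 / (2 * w_px^2))
}

# A small two-phenotype scene: marker-positive cells at rate 8 dots/cell,
# negatives at background rate.
small_scene <- function(n_cells = 30, frame = c(160, 160), seed = 7,
                        pos_frac = 0.5) {
  generate_layout(
    n_cells, frame, c(8, 14),
    phenotype_mix = c(pos = pos_frac, neg = 1 - pos_frac),
    phenotypes = list(phenotype_spec("pos", c(rna_1 = 8)),
                      phenotype_spec("neg", c(rna_1 = 0.2))),
    rng_seed = seed)
}

noiseless_optics <- function(side = 320, seed = 3) {
  optics_config(tile_side_px = side, noise_gaussian_sd = 0,
                noise_poisson_scale = 0, rng_seed = seed)
}

# Plain cell table built directly (no imaging) for table-level tests.
toy_cell_table <- function(n, seed = 1, frame = 900,
                           layout = mosaic_layout(1, 1, 2048, 48, 0.5)) {
  withr::with_seed(seed, {
    tab <- tibble::tibble(
      cell_id = seq_len(n),
      x_um = runif(n, 30, frame), y_um = runif(n, 30, frame),
      area_um2 = pi * runif(n, 4, 7)^2,
      tile_row = 0L, tile_col = 0L, nuclei = 1L,
      CD19 = rbinom(n, 1, 0.1) * 5L,
      GZMB = rpois(n, 1), ihc = 0)
  })
  attr(tab, "layout") <- layout
  attr(tab, "rna_roles") <- c("CD19", "GZMB")
  class(tab) <- c("cell_table", class(tab))
  tab
}

# Brute-force O(n^2) connected components of the expanded-circle overlap
# graph: the independent oracle for the partition grouping.
brute_force_groups <- function(x, y, R) {
  n <- length(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 < (R[i] + R[j])^2 &&
            comp[i] != comp[j]) {
          m <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
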