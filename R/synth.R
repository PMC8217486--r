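# Synthetic multichannel scene generator with exact ground truth.
#
# Emulates WGA membrane ridges around convex cells, DAPI nuclei blobs,
# punctate RNA FISH dots at per-phenotype Poisson rates, diffuse IHC fill,
# multiplicative Gaussian vignetting and Poisson + Gaussian noise. The
# ground truth (polygons, phenotypes, per-cell spot counts) is the oracle
# for segmentation and counting recovery tests.

#' Imaging/optics configuration for the synthetic renderer
#'
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param tile_side_px Tile side in pixels (>= 128).
#' @param membrane_ridge_width_px Gaussian half-width of the rendered
#'   membrane ridge, in pixels.
#' @param ridge_contrast Peak ridge intensity above background.
#' @param vignette_sigma_frac Vignette Gaussian sigma as a fraction of the
#'   tile side; the gain peaks at 1 in the tile centre.
#' @param noise_gaussian_sd Additive Gaussian read-noise SD.
#' @param noise_poisson_scale Photon scaling for Poisson shot noise
#'   (`0` disables it).
#' @param base_level Uniform background intensity.
#' @param spot_sigma_um Rendered FISH dot sigma (sub-resolution).
#' @param spot_amplitude Peak FISH dot intensity.
#' @param nucleus_sigma_um Rendered nucleus blob sigma.
#' @param nucleus_amplitude Peak nucleus intensity.
#' @param rng_seed Integer seed driving all rendering randomness.
#' @return An `optics_config` object.
#' @export
optics_config <- function(pixel_size_um = 0.5, tile_side_px = 512L,
                          membrane_ridge_width_px = 2,
                          ridge_contrast = 120,
                          vignette_sigma_frac = 0.6,
                          noise_gaussian_sd = 2,
                          noise_poisson_scale = 1,
                          base_level = 8,
                          spot_sigma_um = 0.4, spot_amplitude = 150,
                          nucleus_sigma_um = 2, nucleus_amplitude = 100,
                          rng_seed = 1L) {
  if (pixel_size_um <= 0) abort("pixel_size_um must be > 0")
  if (tile_side_px < 128) abort("tile_side_px must be >= 128")
  if (noise_gaussian_sd < 0 || noise_poisson_scale < 0) {
    abort("noise parameters must be >= 0")
  }
  structure(as.list(environment()), class = "optics_config")
}

#' Cell phenotype specification
#'
#' Defines one synthetic cell population: mean FISH dots per cell for each
#' RNA channel (Poisson rates), diffuse IHC fill intensity, and nuclei per
#' cell. Stands in for marker combinations such as CAR / CD4 / CD8a / GZMB /
#' IFNg-positive T cells and CD19+ tumour cells.
#'
#' @param name Phenotype label.
#' @param rate_per_channel Named numeric vector of mean dots/cell, names in
#'   `c("rna_1", "rna_2")`; finite and >= 0.
#' @param ihc_level Mean IHC fill intensity.
#' @param nuclei_per_cell Integer >= 1.
#' @return A `phenotype_spec` object.
#' @export
phenotype_spec <- function(name, rate_per_channel = c(rna_1 = 0),
                           ihc_level = 0, nuclei_per_cell = 1L) {
  if (any(!is.finite(rate_per_channel)) || any(rate_per_channel < 0)) {
    abort("rates must be finite and >= 0")
  }
  if (nuclei_per_cell < 1) abort("nuclei_per_cell must be >= 1")
  structure(list(name = name, rate_per_channel = rate_per_channel,
                 ihc_level = ihc_level,
                 nuclei_per_cell = as.integer(nuclei_per_cell)),
            class = "phenotype_spec")
}

# Random convex polygon approximating a roundish cell: radial perturbation
# of a base circle (<= `pert` relative), then convex hull.
convex_cell_polygon <- function(cx, cy, r, n_vert = 14L, pert = 0.18) {
  ang <- sort(runif(n_vert, 0, 2 * pi))
  rad <- r * (1 + runif(n_vert, -pert, pert))
  pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]  # counter-clockwise
}

# Sample `k` points uniformly inside a polygon with a minimum pairwise
# separation and a margin from the boundary (FISH dots are cytosolic and sit
# inside the plasma membrane, not on it); both constraints are relaxed after
# repeated failures so the requested count is always met (count conservation
# matters more than spacing).
sample_points_in_polygon <- function(poly, k, min_sep = 0, margin = 0) {
  if (k == 0) return(cbind(x = double(), y = double()))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  pts <- matrix(NA_real_, k, 2)
  placed <- 0L; tries <- 0L; sep <- min_sep; mar <- margin
  while (placed < k) {
    x <- runif(1, xr[1], xr[2]); y <- runif(1, yr[1], yr[2])
    tries <- tries + 1L
    ok <- points_in_polygon(x, y, poly)
    if (ok && mar > 0) ok <- dist_to_segments(x, y, poly) >= mar
    if (ok && placed > 0 && sep > 0) {
      d2 <- (pts[seq_len(placed), 1] - x)^2 + (pts[seq_len(placed), 2] - y)^2
      ok <- all(d2 >= sep^2)
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(x, y)
      tries <- 0L
    } else if (tries > 200L) {
      # relax: a tiny cell cannot hold k separated inset dots
      sep <- sep / 2
      mar <- mar / 2
      tries <- 0L
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate a synthetic cell scene with ground truth
#'
#' Places `n_cells` convex cells in a frame by rejection sampling without
#' overlap, assigns phenotypes by largest-remainder apportionment of the
#' requested mix, and draws per-cell FISH dot counts from each phenotype's
#' Poisson rates. All randomness flows from `rng_seed`.
#'
#' @param n_cells Number of cells (>= 0).
#' @param frame_um Frame size `c(width, height)` in micrometres.
#' @param diameter_range_um Cell diameter range, within \[3, 50\] um.
#' @param phenotype_mix Named fractions summing to 1; names must match
#'   `phenotypes`.
#' @param phenotypes List of [phenotype_spec()]s.
#' @param rng_seed Integer seed.
#' @param phenotype_counts Optional named integer counts overriding
#'   `phenotype_mix` (used by [make_dilution_series()]).
#' @param overlap_policy `"none"` (default, rejection sampling) or `"abut"`
#'   (cells may touch and share membrane ridges, as in dense tissue).
#' @param cluster Optional [cluster_spec()] planting a spatial cluster in
#'   which the named phenotypes are enriched.
#' @param min_dot_sep_um Minimum separation between dots within a cell
#'   (diffraction-resolvable dots); relaxed if a cell is too small.
#' @param dot_margin_um Minimum distance of dots from the cell boundary
#'   (dots are cytosolic, inside the plasma membrane); relaxed if needed.
#' @param max_attempts Placement attempts per cell before giving up.
#' @return A `ground_truth` object: `$cells` is a tibble with `cell_id`,
#'   `phenotype`, `x_um`, `y_um`, `radius_um`, list-columns `polygon`
#'   (micrometre vertex matrices), `nuclei`, `spots` (per RNA role), and
#'   `ihc_level`; plus `$frame_um`, `$phenotypes`, `$rng_seed`.
#' @examples
#' gt <- generate_layout(20, c(120, 120), c(8, 14),
#'                       phenotype_mix = c(pos = 0.25, neg = 0.75),
#'                       phenotypes = list(
#'                         phenotype_spec("pos", c(rna_1 = 8)),
#'                         phenotype_spec("neg", c(rna_1 = 0.2))),
#'                       rng_seed = 7)
#' table(gt$cells$phenotype)
#' @export
generate_layout <- function(n_cells, frame_um, diameter_range_um = c(8, 14),
                            phenotype_mix = c(cell = 1),
                            phenotypes = list(phenotype_spec("cell")),
                            rng_seed = 1L,
                            phenotype_counts = NULL,
                            overlap_policy = c("none", "abut"),
                            cluster = NULL,
                            min_dot_sep_um = 1.5,
                            dot_margin_um = 1.0,
                            max_attempts = 5000L) {
  overlap_policy <- match.arg(overlap_policy)
  if (n_cells < 0) abort("n_cells must be >= 0")
  if (diameter_range_um[1] < 3 || diameter_range_um[2] > 50) {
    abort("diameters must lie within [3, 50] um")
  }
  pheno_names <- vapply(phenotypes, `[[`, "", "name")
  names(phenotypes) <- pheno_names
  if (is.null(phenotype_counts)) {
    if (abs(sum(phenotype_mix) - 1) > 1e-9) {
      abort("phenotype_mix fractions must sum to 1")
    }
    if (!all(names(phenotype_mix) %in% pheno_names)) {
      abort("phenotype_mix names must match phenotypes")
    }
    counts <- largest_remainder(n_cells, phenotype_mix)
    names(counts) <- names(phenotype_mix)
  } else {
    counts <- phenotype_counts
    if (sum(counts) != n_cells) abort("phenotype_counts must sum to n_cells")
  }
  rna_roles <- sort(unique(unlist(lapply(phenotypes, function(p)
    names(p$rate_per_channel)))))

  gt_cells <- with_rng(rng_seed, {
    labels <- rep(names(counts), counts)
    if (length(labels)) labels <- sample(labels)  # interleave phenotypes
    rmax <- diameter_range_um[2] / 2 * 1.2       # max possible vertex radius
    margin <- rmax + 1
    W <- frame_um[1]; H <- frame_um[2]
    if (W <= 2 * margin || H <= 2 * margin) {
      abort("frame too small for the requested cell sizes")
    }
    cx <- double(n_cells); cy <- double(n_cells); rr <- double(n_cells)
    for (i in seq_len(n_cells)) {
      r <- runif(1, diameter_range_um[1] / 2, diameter_range_um[2] / 2)
      placed <- FALSE
      enrich_here <- !is.null(cluster) && labels[i] %in% cluster$phenotypes
      for (a in seq_len(max_attempts)) {
        if (enrich_here) {
          # enrichment e: density inside cluster disc e times the outside
          a_c <- pi * cluster$radius_um^2
          p_in <- cluster$enrichment * a_c /
            (cluster$enrichment * a_c + (W * H - a_c))
          if (runif(1) < p_in) {
            th <- runif(1, 0, 2 * pi); rad <- cluster$radius_um * sqrt(runif(1))
            x <- cluster$center_um[1] + rad * cos(th)
            y <- cluster$center_um[2] + rad * sin(th)
            x <- min(max(x, margin), W - margin)
            y <- min(max(y, margin), H - margin)
          } else {
            x <- runif(1, margin, W - margin); y <- runif(1, margin, H - margin)
          }
        } else {
          x <- runif(1, margin, W - margin); y <- runif(1, margin, H - margin)
        }
        if (i == 1) { placed <- TRUE }
        else {
          prev <- seq_len(i - 1)
          d2 <- (cx[prev] - x)^2 + (cy[prev] - y)^2
          lim <- if (overlap_policy == "none") {
            (1.2 * r + 1.2 * rr[prev] + 0.5)^2
          } else {
            (0.75 * (r + rr[prev]))^2  # abutting: membranes may share
          }
          placed <- all(d2 >= lim)
        }
        if (placed) break
      }
      if (!placed) {
        dens <- (i - 1) / (W * H / 1e6)
        abort(sprintf(
          "cell placement failed after %d attempts at %d cells (%.0f cells/mm^2); enlarge frame_um or reduce n_cells",
          max_attempts, i - 1, dens))
      }
      cx[i] <- x; cy[i] <- y; rr[i] <- r
    }
    polys <- vector("list", n_cells)
    nucs <- vector("list", n_cells)
    spots <- vector("list", n_cells)
    true_counts <- matrix(0L, n_cells, length(rna_roles),
                          dimnames = list(NULL, rna_roles))
    for (i in seq_len(n_cells)) {
      ph <- phenotypes[[labels[i]]]
      polys[[i]] <- convex_cell_polygon(cx[i], cy[i], rr[i])
      k_nuc <- ph$nuclei_per_cell
      offs <- matrix(runif(2 * k_nuc, -0.3 * rr[i], 0.3 * rr[i]), ncol = 2)
      nucs[[i]] <- cbind(x = cx[i] + offs[, 1], y = cy[i] + offs[, 2])
      sp <- list()
      for (role in rna_roles) {
        rate <- ph$rate_per_channel[role]
        k <- if (is.na(rate)) 0L else rpois(1, rate)
        true_counts[i, role] <- k
        sp[[role]] <- sample_points_in_polygon(polys[[i]], k, min_dot_sep_um,
                                               dot_margin_um)
      }
      spots[[i]] <- sp
    }
    tibble(
      cell_id = seq_len(n_cells),
      phenotype = labels %||% character(0),
      x_um = cx, y_um = cy, radius_um = rr,
      polygon = polys, nuclei = nucs, spots = spots,
      ihc_level = vapply(labels, function(l) phenotypes[[l]]$ihc_level, 1)
    )
  })
  if (n_cells == 0) {
    gt_cells <- tibble(cell_id = integer(), phenotype = character(),
                       x_um = double(), y_um = double(), radius_um = double(),
                       polygon = list(), nuclei = list(), spots = list(),
                       ihc_level = double())
  }
  structure(list(cells = gt_cells, frame_um = as.numeric(frame_um),
                 rna_roles = rna_roles, phenotypes = phenotypes,
                 overlap_policy = overlap_policy, rng_seed = rng_seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells in %.0f x %.0f um, phenotypes: %s\n",
              nrow(x$cells), x$frame_um[1], x$frame_um[2],
              paste(names(x$phenotypes), collapse = ", ")))
  invisible(x)
}

#' @rdname generate_layout
#' @param center_um,radius_um Cluster disc centre and radius (um).
#' @param enrichment Density enrichment factor inside the cluster.
#' @export
cluster_spec <- function(center_um, radius_um, phenotypes, enrichment = 5) {
  list(center_um = as.numeric(center_um), radius_um = radius_um,
       phenotypes = phenotypes, enrichment = enrichment)
}

#' True per-cell spot counts of a scene
#'
#' @param gt A `ground_truth`.
#' @return Tibble `cell_id`, `phenotype`, one column per RNA role.
#' @export
true_counts <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  out <- gt$cells[, c("cell_id", "phenotype")]
  for (role in gt$rna_roles) {
    out[[role]] <- map_int(gt$cells$spots, function(s) {
      m <- s[[role]]
      if (is.null(m)) 0L else nrow(m)
    })
  }
  out
}

#' Synthetic dilution series of marker-positive cells
#'
#' Emulates the in-vitro validation design in which CAR T cells of known
#' flow-cytometric purity are mixed with marker-negative cells at a ladder
#' of ratios and spun onto slides: scene `i` contains
#' `round(n_cells * ratio_i * purity)` marker-positive cells, the remainder
#' negative. With purity 0.90 and ratios 1, 0.75, 0.5, 0.25, 0 the expected
#' positive fractions are 90%, 67.5%, 45%, 22.5% and 0%.
#'
#' @param purity Fraction of the positive stock that truly expresses the
#'   marker, in \[0, 1\].
#' @param ratios Mixing ratios, each in \[0, 1\].
#' @param n_cells Cells per scene.
#' @param rng_seed Integer seed; scene `i` uses a derived sub-seed.
#' @param frame_um Frame size; sized automatically if `NULL`.
#' @param positive,negative [phenotype_spec()]s for the two populations.
#' @param diameter_range_um Cell diameter range.
#' @return List of `ground_truth` scenes, one per ratio, each carrying
#'   attributes `ratio`, `purity` and `n_positive`.
#' @export
make_dilution_series <- function(purity = 0.9,
                                 ratios = c(1, 0.75, 0.5, 0.25, 0),
                                 n_cells = 1000L, rng_seed = 1L,
                                 frame_um = NULL,
                                 positive = phenotype_spec(
                                   "car_pos", c(rna_1 = 8), nuclei_per_cell = 1),
                                 negative = phenotype_spec(
                                   "car_neg", c(rna_1 = 0.2), nuclei_per_cell = 1),
                                 diameter_range_um = c(8, 14)) {
  if (purity < 0 || purity > 1) abort("purity must be in [0, 1]")
  if (any(ratios < 0 | ratios > 1)) abort("ratios must be in [0, 1]")
  if (is.null(frame_um)) {
    # target ~22% packing of mean-size cells
    rbar <- mean(diameter_range_um) / 2
    side <- sqrt(n_cells * pi * rbar^2 / 0.22)
    frame_um <- c(side, side)
  }
  imap(as.list(ratios), function(ratio, i) {
    n_pos <- as.integer(round(n_cells * ratio * purity))
    gt <- generate_layout(
      n_cells, frame_um, diameter_range_um,
      phenotypes = list(positive, negative),
      phenotype_counts = c(n_pos, n_cells - n_pos) |>
        stats::setNames(c(positive$name, negative$name)),
      rng_seed = derive_seed(rng_seed, i))
    attr(gt, "ratio") <- ratio
    attr(gt, "purity") <- purity
    attr(gt, "n_positive") <- n_pos
    gt
  })
}

#' Honeycomb phantom: densely abutting cells with shared membranes
#'
#' A hexagonal lattice of cells sharing every membrane edge — the hardest
#' regime for loop segmentation, mimicking confluent tissue. Ground-truth
#' polygons are the hexagons.
#'
#' @param n_rows,n_cols Lattice dimensions (`n_rows * n_cols` cells).
#' @param hex_radius_um Hexagon circumradius in micrometres.
#' @param rng_seed Seed for the (small) vertex jitter.
#' @param jitter_um SD of vertex jitter; 0 for a perfect lattice.
#' @param frame_um Optional frame size; enlarged to fit the lattice.
#' @return A `ground_truth` with a single phenotype `"cell"`.
#' @export
honeycomb_layout <- function(n_rows = 10L, n_cols = 10L, hex_radius_um = 7,
                             rng_seed = 1L, jitter_um = 0, frame_um = NULL) {
  R <- hex_radius_um
  w <- sqrt(3) * R           # horizontal pitch (pointy-top hexes)
  margin <- 2 * R + 4
  centers <- list()
  for (i in seq_len(n_rows) - 1L) {
    for (j in seq_len(n_cols) - 1L) {
      x <- margin + j * w + (i %% 2) * w / 2
      y <- margin + i * 1.5 * R
      centers[[length(centers) + 1L]] <- c(x, y)
    }
  }
  ctr <- do.call(rbind, centers)
  frame <- c(max(ctr[, 1]) + margin, max(ctr[, 2]) + margin)
  if (!is.null(frame_um)) frame <- pmax(frame, frame_um)
  ang <- pi / 6 + (0:5) * pi / 3   # pointy-top hexagon
  cells <- with_rng(rng_seed, {
    polys <- lapply(seq_len(nrow(ctr)), function(i) {
      vx <- ctr[i, 1] + R * cos(ang)
      vy <- ctr[i, 2] + R * sin(ang)
      if (jitter_um > 0) {
        vx <- vx + rnorm(6, 0, jitter_um)
        vy <- vy + rnorm(6, 0, jitter_um)
      }
      cbind(vx, vy)
    })
    tibble(
      cell_id = seq_len(nrow(ctr)), phenotype = "cell",
      x_um = ctr[, 1], y_um = ctr[, 2], radius_um = R,
      polygon = polys,
      nuclei = lapply(seq_len(nrow(ctr)), function(i)
        cbind(x = ctr[i, 1], y = ctr[i, 2])),
      spots = rep(list(list(rna_1 = cbind(x = double(), y = double()))),
                  nrow(ctr)),
      ihc_level = 0
    )
  })
  structure(list(cells = cells, frame_um = frame, rna_roles = "rna_1",
                 phenotypes = list(cell = phenotype_spec("cell")),
                 overlap_policy = "abut", rng_seed = rng_seed),
            class = "ground_truth")
}

# Additive Gaussian splat of unit peak at (x, y) um into canvas (px frame).
splat_gaussians <- function(canvas, xs_um, ys_um, sigma_px, amp, pix) {
  if (!length(xs_um)) return(canvas)
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(4 * sigma_px)
  for (i in seq_along(xs_um)) {
    x0 <- xs_um[i] / pix; y0 <- ys_um[i] / pix
    xs <- max(0, floor(x0 - r)):min(w - 1, ceiling(x0 + r))
    ys <- max(0, floor(y0 - r)):min(h - 1, ceiling(y0 + r))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - x0)^2 / (2 * sigma_px^2))
    gy <- exp(-(ys - y0)^2 / (2 * sigma_px^2))
    canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + amp * outer(gy, gx)
  }
  canvas
}

#' Render a scene into mosaic tiles
#'
#' Rasterises the ground truth onto a global canvas — membrane ridges along
#' every cell boundary, nuclei blobs, sub-resolution FISH dots, diffuse IHC
#' fill — then cuts tiles, applies a centred multiplicative Gaussian
#' vignette per tile and adds Poisson and Gaussian noise. Cells spanning
#' tile borders are rendered consistently in all covering tiles because the
#' scene is rendered once globally.
#'
#' @param gt A `ground_truth`; its frame must cover the layout extent.
#' @param optics An [optics_config()].
#' @param layout A [mosaic_layout()]; pixel sizes and tile sides must match
#'   `optics`.
#' @param channels Channel roles to render (subset of nuclei, membrane,
#'   rna_1, rna_2, ihc; membrane always included).
#' @return List of [tile_image()]s in row-major tile order.
#' @export
render_tiles <- function(gt, optics, layout,
                         channels = c("membrane", "nuclei", gt$rna_roles,
                                      if (any(gt$cells$ihc_level > 0)) "ihc")) {
  stopifnot(inherits(gt, "ground_truth"), inherits(optics, "optics_config"),
            inherits(layout, "mosaic_layout"))
  if (layout$side_px != optics$tile_side_px ||
      abs(layout$pixel_size_um - optics$pixel_size_um) > 1e-12) {
    abort("optics and layout disagree on tile side or pixel size")
  }
  pix <- optics$pixel_size_um
  W_px <- layout$n_cols * layout$side_px
  H_px <- layout$n_rows * layout$side_px
  if (gt$frame_um[1] < (W_px - 1) * pix || gt$frame_um[2] < (H_px - 1) * pix) {
    abort("ground-truth frame does not cover the layout extent")
  }
  channels <- unique(c("membrane", channels))
  canvases <- lapply(channels, function(ch)
    matrix(optics$base_level, H_px, W_px))
  names(canvases) <- channels

  wpx <- optics$membrane_ridge_width_px
  for (i in seq_len(nrow(gt$cells))) {
    poly_px <- gt$cells$polygon[[i]] / pix
    # membrane ridge: Gaussian profile of distance to the polygon boundary
    reach <- 3 * wpx
    xs <- max(0, floor(min(poly_px[, 1]) - reach)):
      min(W_px - 1, ceiling(max(poly_px[, 1]) + reach))
    ys <- max(0, floor(min(poly_px[, 2]) - reach)):
      min(H_px - 1, ceiling(max(poly_px[, 2]) + reach))
    if (length(xs) && length(ys)) {
      g <- expand.grid(x = xs, y = ys)
      d <- dist_to_segments(g$x, g$y, poly_px)
      ridge <- optics$ridge_contrast * exp(-d^2 / (2 * wpx^2))
      idx <- cbind(g$y + 1L, g$x + 1L)
      # shared membranes between abutting neighbours stay single-bright
      canvases$membrane[idx] <- pmax(canvases$membrane[idx],
                                     optics$base_level + ridge)
      if ("ihc" %in% channels && gt$cells$ihc_level[i] > 0) {
        inside <- points_in_polygon(g$x, g$y, poly_px)
        canvases$ihc[idx[inside, , drop = FALSE]] <-
          canvases$ihc[idx[inside, , drop = FALSE]] + gt$cells$ihc_level[i]
      }
    }
    if ("nuclei" %in% channels) {
      nuc <- gt$cells$nuclei[[i]]
      canvases$nuclei <- splat_gaussians(
        canvases$nuclei, nuc[, 1], nuc[, 2],
        optics$nucleus_sigma_um / pix, optics$nucleus_amplitude, pix)
    }
    for (role in intersect(gt$rna_roles, channels)) {
      sp <- gt$cells$spots[[i]][[role]]
      if (!is.null(sp) && nrow(sp)) {
        canvases[[role]] <- splat_gaussians(
          canvases[[role]], sp[, 1], sp[, 2],
          optics$spot_sigma_um / pix, optics$spot_amplitude, pix)
      }
    }
  }

  s <- layout$side_px
  cx <- (s - 1) / 2
  xg <- matrix(rep(0:(s - 1), each = s), s, s)
  yg <- matrix(rep(0:(s - 1), s), s, s)
  vsig <- optics$vignette_sigma_frac * s
  gain <- exp(-((xg - cx)^2 + (yg - cx)^2) / (2 * vsig^2))

  tiles <- list()
  for (row in seq_len(layout$n_rows) - 1L) {
    for (col in seq_len(layout$n_cols) - 1L) {
      chans <- lapply(canvases, function(cv)
        cv[row * s + seq_len(s), col * s + seq_len(s)])
      chans <- lapply(chans, function(m) m * gain)
      tile_seed <- derive_seed(optics$rng_seed, row * layout$n_cols + col)
      chans <- with_rng(tile_seed, lapply(chans, function(m) {
        if (optics$noise_poisson_scale > 0) {
          m <- rpois(length(m), as.vector(m) * optics$noise_poisson_scale) /
            optics$noise_poisson_scale
          m <- matrix(m, s, s)
        }
        if (optics$noise_gaussian_sd > 0) {
          m <- m + matrix(rnorm(length(m), 0, optics$noise_gaussian_sd), s, s)
        }
        pmax(m, 0)
      }))
      tiles[[length(tiles) + 1L]] <- tile_image(
        chans, pixel_size_um = pix, grid_pos = c(row, col))
    }
  }
  tiles
}

#' Write a scene's ground truth as a JSON sidecar
#'
#' Polygons are vertex lists in micrometres, 0-based, x along columns and y
#' along rows.
#'
#' @param gt A `ground_truth`.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  cells <- lapply(seq_len(nrow(gt$cells)), function(i) {
    r <- gt$cells[i, ]
    list(cell_id = r$cell_id, phenotype = r$phenotype,
         x_um = r$x_um, y_um = r$y_um,
         polygon = unname(apply(r$polygon[[1]], 1, as.list)),
         nuclei = unname(apply(r$nuclei[[1]], 1, as.list)),
         spots = lapply(r$spots[[1]], function(m)
           unname(apply(m, 1, as.list))),
         ihc_level = r$ihc_level)
  })
  jsonlite::write_json(
    list(frame_um = gt$frame_um, rna_roles = gt$rna_roles, cells = cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
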