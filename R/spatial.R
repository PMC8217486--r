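# Tissue partition by circle expansion around marker-positive tumour cells,
# spatial densities per mm^2, and the accompanying significance tests.

#' Partition parameters
#'
#' @param expansion_factor Each marker-positive cell's equivalent circle
#'   (radius `sqrt(area/pi)`) is expanded by this factor (> 1; the working
#'   value is about 16).
#' @param largest_by How to pick the winning connective group:
#'   `"member_count"` (ties by larger disc-union area) or `"union_area"`.
#' @return A `partition_params` object.
#' @export
partition_params <- function(expansion_factor = 16,
                             largest_by = c("member_count", "union_area")) {
  if (expansion_factor <= 1) abort("expansion_factor must be > 1")
  structure(list(expansion_factor = expansion_factor,
                 largest_by = match.arg(largest_by)),
            class = "partition_params")
}

disc_polygon <- function(cx, cy, r, n = 48L) {
  th <- 2 * pi * (0:(n - 1)) / n
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

poly_list_area <- function(polys) {
  # polyclip output: outer contours and holes carry opposite orientation;
  # the signed shoelace sum is the net enclosed area
  abs(sum(vapply(polys, function(p)
    polygon_signed_area(cbind(p$x, p$y)), 1)))
}

union_polys <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  polyclip::polyclip(a, b, op = "union")
}

# Union of discs as polyclip contour list (64-gon discs, coordinates um).
discs_union <- function(cx, cy, r) {
  out <- list()
  for (i in seq_along(cx)) {
    out <- union_polys(out, list(disc_polygon(cx[i], cy[i], r[i], 64L)))
  }
  out
}

# Occupied-tile analysis rectangles as polyclip contours (um).
tissue_polys <- function(table, layout) {
  occ <- unique(table[, c("tile_row", "tile_col")])
  s <- layout$side_px; b <- layout$border_px; pix <- layout$pixel_size_um
  lapply(seq_len(nrow(occ)), function(i) {
    x0 <- (occ$tile_col[i] * s + b) * pix
    x1 <- (occ$tile_col[i] * s + s - b) * pix
    y0 <- (occ$tile_row[i] * s + b) * pix
    y1 <- (occ$tile_row[i] * s + s - b) * pix
    list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  })
}

#' Analysed tissue area
#'
#' The analysed tissue area is the summed analysis-mask area of tiles
#' containing at least one detected cell (converted to mm^2 via the pixel
#' size). The alternative `method = "hull"` uses the convex hull of the
#' cell centroids instead.
#'
#' @param table A `cell_table`.
#' @param layout A [mosaic_layout()]; defaults to the table's metadata.
#' @param method `"tiles"` (default) or `"hull"`.
#' @return Area in mm^2 (0, with a message, for an empty table).
#' @examples
#' # one occupied 2048 px tile, 48 px border, 0.5 um pixels:
#' # (1952 * 0.5 / 1000)^2 = 0.952576 mm^2
#' @export
tissue_area <- function(table, layout = attr(table, "layout"),
                        method = c("tiles", "hull")) {
  method <- match.arg(method)
  if (!nrow(table)) {
    warn("empty table: tissue area 0")
    return(0)
  }
  if (method == "hull") {
    h <- grDevices::chull(table$x_um, table$y_um)
    return(polygon_area(cbind(table$x_um[h], table$y_um[h])) / 1e6)
  }
  stopifnot(inherits(layout, "mosaic_layout"))
  occ <- unique(table[, c("tile_row", "tile_col")])
  s <- layout$side_px; b <- layout$border_px
  nrow(occ) * ((s - 2 * b) * layout$pixel_size_um / 1000)^2
}

#' Partition tissue into marker-high and marker-low areas
#'
#' Implements the circle-expansion construction: every marker-positive cell
#' contributes a circle of its equivalent radius `r = sqrt(area/pi)`
#' expanded by `expansion_factor`; cells whose expanded circles overlap
#' (centroid distance below the sum of expanded radii) form connective
#' groups; the largest group's disc union — clipped to the analysed tissue —
#' is the marker-high region and the remainder of the tissue the marker-low
#' region. Every cell in the table is assigned to exactly one region by the
#' centroid-in-disc-union rule.
#'
#' @param table A `cell_table`.
#' @param marker_gate A [gate_spec()] selecting marker-positive cells
#'   (e.g. CD19+ tumour cells via [ihc_gate()]).
#' @param params A [partition_params()].
#' @param layout A [mosaic_layout()]; defaults to the table's metadata.
#' @return An `area_partition`: `high_polys` (contour list, um),
#'   `area_high_mm2`, `area_low_mm2`, `area_tissue_mm2`, `member_ids`,
#'   `assignment` tibble (`cell_id`, `region`), `n_groups`, and an
#'   `empty_high` flag when there are no marker-positive cells.
#' @export
cd19_partition <- function(table, marker_gate,
                           params = partition_params(),
                           layout = attr(table, "layout")) {
  if (!nrow(table)) abort("table must be non-empty")
  g <- gate_cells(table, marker_gate)
  pos <- table[g$membership$positive, ]
  a_tissue <- tissue_area(table, layout)
  if (!nrow(pos)) {
    warn("no marker-positive cells: high region is empty")
    return(structure(
      list(high_polys = list(), area_high_mm2 = 0,
           area_low_mm2 = a_tissue, area_tissue_mm2 = a_tissue,
           member_ids = integer(),
           assignment = tibble(cell_id = table$cell_id, region = "low"),
           n_groups = 0L, empty_high = TRUE, params = params),
      class = "area_partition"))
  }
  r <- sqrt(pos$area_um2 / pi)
  R <- params$expansion_factor * r
  n <- nrow(pos)
  # connective groups: overlapping expanded circles
  d <- as.matrix(stats::dist(cbind(pos$x_um, pos$y_um)))
  adj <- d < outer(R, R, `+`)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  groups <- split(seq_len(n), comp)
  areas <- map_dbl(groups, function(ix)
    poly_list_area(discs_union(pos$x_um[ix], pos$y_um[ix], R[ix])))
  sizes <- lengths(groups)
  win <- if (params$largest_by == "member_count") {
    order(-sizes, -areas)[1]
  } else {
    order(-areas, -sizes)[1]
  }
  mem <- groups[[win]]
  member_ids <- pos$cell_id[mem]
  high_discs <- discs_union(pos$x_um[mem], pos$y_um[mem], R[mem])
  high_polys <- polyclip::polyclip(high_discs, tissue_polys(table, layout),
                                   op = "intersection")
  a_high <- poly_list_area(high_polys) / 1e6
  # centroid-in-disc-union assignment (exact, no rasterisation)
  in_high <- map_lgl(seq_len(nrow(table)), function(i) {
    any((table$x_um[i] - pos$x_um[mem])^2 +
          (table$y_um[i] - pos$y_um[mem])^2 <= R[mem]^2)
  })
  structure(
    list(high_polys = high_polys, area_high_mm2 = a_high,
         area_low_mm2 = a_tissue - a_high, area_tissue_mm2 = a_tissue,
         member_ids = member_ids,
         assignment = tibble(cell_id = table$cell_id,
                             region = ifelse(in_high, "high", "low")),
         n_groups = length(groups), empty_high = FALSE, params = params),
    class = "area_partition")
}

#' @export
print.area_partition <- function(x, ...) {
  cat(sprintf(
    "<area_partition> high %.4g mm^2 (%d member cells, %d groups), low %.4g mm^2 of %.4g mm^2\n",
    x$area_high_mm2, length(x$member_ids), x$n_groups, x$area_low_mm2,
    x$area_tissue_mm2))
  invisible(x)
}

#' Spatial density of phenotypes per region
#'
#' For each phenotype gate and each region of the partition, counts gated
#' cells and divides by the region area (cells per mm^2). Optional ratio
#' rows compare two phenotypes within each region (computed only where the
#' denominator count is positive).
#'
#' @param table A `cell_table`.
#' @param partition An `area_partition` covering the table.
#' @param gates List of [gate_spec()]s.
#' @param ratio_pairs Optional list of `c(numerator_label,
#'   denominator_label)` pairs.
#' @return A `density_summary` tibble: `phenotype`, `region`, `count`,
#'   `area_mm2`, `density_mm2`; ratio rows are carried in the `ratios`
#'   attribute as a tibble (`numerator`, `denominator`, `region`, `ratio`).
#' @export
spatial_density <- function(table, partition, gates, ratio_pairs = NULL) {
  stopifnot(inherits(partition, "area_partition"))
  if (!all(table$cell_id %in% partition$assignment$cell_id)) {
    abort("partition does not cover the table")
  }
  region <- partition$assignment$region[
    match(table$cell_id, partition$assignment$cell_id)]
  areas <- c(high = partition$area_high_mm2, low = partition$area_low_mm2)
  rows <- list()
  for (gs in gates) {
    pos <- gate_cells(table, gs)$membership$positive
    for (rg in c("high", "low")) {
      cnt <- sum(pos & region == rg)
      if (cnt > 0 && areas[[rg]] <= 0) {
        abort(sprintf("region %s has zero area but %d cells: inconsistent partition",
                      rg, cnt))
      }
      rows[[length(rows) + 1L]] <- tibble(
        phenotype = gs$label, region = rg, count = cnt,
        area_mm2 = areas[[rg]],
        density_mm2 = if (areas[[rg]] > 0) cnt / areas[[rg]] else 0)
    }
  }
  out <- bind_rows(rows)
  ratios <- NULL
  if (!is.null(ratio_pairs)) {
    ratios <- bind_rows(map(ratio_pairs, function(pr) {
      bind_rows(map(c("high", "low"), function(rg) {
        num <- out$density_mm2[out$phenotype == pr[1] & out$region == rg]
        den <- out$density_mm2[out$phenotype == pr[2] & out$region == rg]
        tibble(numerator = pr[1], denominator = pr[2], region = rg,
               ratio = if (length(den) && den > 0) num / den else NA_real_)
      }))
    }))
  }
  attr(out, "ratios") <- ratios
  class(out) <- c("density_summary", class(out))
  out
}

#' Paired t test on per-section values
#'
#' Two-sided paired t test comparing matched per-section measurements
#' (e.g. a phenotype's density in the marker-high vs marker-low area of
#' each section): `t = mean(d) / (sd(d)/sqrt(n))` on the differences
#' `d = x - y`, `df = n - 1`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`.
#' @return Tibble `t`, `df`, `p`.
#' @examples
#' paired_t(c(2, 2, 2, 0), c(1, 1, 1, 1))  # t = 1, df = 3
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2")
  }
  d <- x - y
  if (sd(d) == 0) abort("degenerate pairs: all differences identical")
  tt <- t.test(x, y, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F ratio with the F-distribution p value
#' (equal-variance one-way ANOVA; post-hoc comparisons are out of scope).
#' If the within-group variance is zero while groups differ, `F` is
#' infinite and the result is flagged via the `degenerate` column.
#'
#' @param groups List of numeric vectors, >= 2 groups of n >= 2 each.
#' @return Tibble `F`, `df1`, `df2`, `p`, `degenerate`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df 2, 6
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with n >= 2 each")
  }
  v <- unlist(groups)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  gm <- mean(v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df1 <- length(groups) - 1L
  df2 <- length(v) - length(groups)
  if (ssw == 0 && ssb == 0) abort("F undefined: no variance at all")
  if (ssw == 0) {
    return(tibble(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  }
  ow <- oneway.test(v ~ f, var.equal = TRUE)
  tibble(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]), p = ow$p.value, degenerate = FALSE)
}

#' Export a partition as CSV (+ GeoJSON-style geometry)
#'
#' Writes the per-cell region assignment as CSV and the high-region
#' contours as a GeoJSON file (micrometre coordinates).
#'
#' @param partition An `area_partition`.
#' @param csv_path,geojson_path Output paths (either may be `NULL`).
#' @export
export_partition <- function(partition, csv_path = NULL,
                             geojson_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(partition$assignment, csv_path, progress = FALSE)
  }
  if (!is.null(geojson_path)) {
    coords <- lapply(partition$high_polys, function(p) {
      m <- cbind(p$x, p$y)
      m <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    })
    gj <- list(type = "Feature",
               properties = list(region = "high",
                                 area_mm2 = partition$area_high_mm2),
               geometry = list(type = "MultiPolygon",
                               coordinates = lapply(coords, list)))
    jsonlite::write_json(gj, geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(partition)
}
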