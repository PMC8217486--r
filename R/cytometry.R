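# Histo-cytometry: assemble the per-cell event table, export it for
# flow-style gating, gate phenotypes, and the dilution-series validation.

#' Assemble the per-cell histo-cytometry table
#'
#' Combines per-tile segmentation and detection results into one table with
#' a record per accepted cell: global centroid in micrometres, area, nuclei
#' count, FISH dot count per RNA channel, and background-subtracted IHC
#' intensity. Loops whose centroid falls in a tile's excluded border strip
#' are dropped (the strip compensates acquisition overlap, so each cell is
#' reported exactly once). Records are ordered by (tile row, tile col,
#' centroid y, centroid x) and numbered 1..n.
#'
#' @param tile_results List of per-tile results from [analyze_tile()].
#' @param layout A [mosaic_layout()].
#' @param rna_names Optional named character vector renaming RNA channel
#'   roles to marker names in the table (e.g. `c(rna_1 = "CAR")`).
#' @return A `cell_table` tibble: `cell_id`, `x_um`, `y_um`, `area_um2`,
#'   `tile_row`, `tile_col`, `nuclei`, one column per RNA marker, `ihc`,
#'   and a `polygon` list-column (global um). Layout, pixel size, channel
#'   roles and applied gates are carried as attributes.
#' @export
build_cell_table <- function(tile_results, layout, rna_names = NULL) {
  stopifnot(inherits(layout, "mosaic_layout"))
  s <- layout$side_px; b <- layout$border_px; pix <- layout$pixel_size_um
  rows <- list()
  for (res in tile_results) {
    loops <- res$loops
    if (!nrow(loops)) next
    gp <- res$grid_pos
    if (gp[1] < 0 || gp[1] >= layout$n_rows ||
        gp[2] < 0 || gp[2] >= layout$n_cols) {
      abort("tile grid position outside layout")
    }
    keep <- loops$centroid_x >= b & loops$centroid_x < s - b &
      loops$centroid_y >= b & loops$centroid_y < s - b
    loops <- loops[keep, ]
    if (!nrow(loops)) next
    glob <- to_global(cbind(loops$centroid_x, loops$centroid_y), gp, layout)
    tb <- tibble(
      x_um = glob$x_um, y_um = glob$y_um,
      area_um2 = loops$area_px2 * pix^2,
      tile_row = gp[1], tile_col = gp[2],
      nuclei = res$nuclei$n[match(loops$loop_id, res$nuclei$loop_id)] %||%
        NA_integer_
    )
    for (role in names(res$dots)) {
      tb[[role]] <- res$dots[[role]]$n[match(loops$loop_id,
                                             res$dots[[role]]$loop_id)]
    }
    tb$ihc <- if (!is.null(res$ihc)) {
      res$ihc$ihc[match(loops$loop_id, res$ihc$loop_id)]
    } else 0
    tb$polygon <- map(loops$polygon, function(p) {
      g <- to_global(p, gp, layout)
      cbind(x_um = g$x_um, y_um = g$y_um)
    })
    rows[[length(rows) + 1L]] <- tb
  }
  rna_roles <- if (length(rows)) {
    setdiff(names(rows[[1]]),
            c("x_um", "y_um", "area_um2", "tile_row", "tile_col", "nuclei",
              "ihc", "polygon"))
  } else character(0)
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(x_um = double(), y_um = double(), area_um2 = double(),
           tile_row = integer(), tile_col = integer(), nuclei = integer(),
           ihc = double(), polygon = list())
  }
  out <- arrange(out, .data$tile_row, .data$tile_col, .data$y_um, .data$x_um)
  out <- mutate(out, cell_id = row_number(), .before = 1)
  if (!is.null(rna_names)) {
    for (role in names(rna_names)) {
      if (role %in% names(out)) {
        names(out)[names(out) == role] <- rna_names[[role]]
        rna_roles[rna_roles == role] <- rna_names[[role]]
      }
    }
  }
  attr(out, "layout") <- layout
  attr(out, "pixel_size_um") <- pix
  attr(out, "rna_roles") <- rna_roles
  attr(out, "gates") <- list()
  class(out) <- c("cell_table", class(out))
  out
}

cell_table_schema <- function(table) {
  rna <- attr(table, "rna_roles") %||%
    setdiff(names(table), c("cell_id", "x_um", "y_um", "area_um2",
                            "tile_row", "tile_col", "nuclei", "ihc",
                            "polygon"))
  c("cell_id", "x_um", "y_um", "area_um2", "nuclei", rna, "ihc")
}

#' Export / import the cell table as CSV
#'
#' Plain numeric-only CSV with a single header line — the event-table
#' dialect that flow-cytometry gating software ingests. Columns:
#' `cell_id,x_um,y_um,area_um2,nuclei,<one per RNA marker>,ihc`. The
#' round-trip is lossless (values are written at full precision).
#'
#' @param table A `cell_table`.
#' @param path CSV path.
#' @export
export_cells_csv <- function(table, path) {
  cols <- cell_table_schema(table)
  df <- as.data.frame(table)[, cols, drop = FALSE]
  if (!all(vapply(df, is.numeric, TRUE))) abort("non-numeric field in table")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_cells_csv
#' @param layout Optional [mosaic_layout()] to re-attach tile positions.
#' @export
import_cells_csv <- function(path, layout = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- as_tibble(df)
  rna <- setdiff(names(out), c("cell_id", "x_um", "y_um", "area_um2",
                               "nuclei", "ihc"))
  if (!is.null(layout)) {
    loc <- to_local(cbind(out$x_um, out$y_um), layout)
    out$tile_row <- as.integer(loc$grid_pos[, "row"])
    out$tile_col <- as.integer(loc$grid_pos[, "col"])
    attr(out, "layout") <- layout
    attr(out, "pixel_size_um") <- layout$pixel_size_um
  }
  attr(out, "rna_roles") <- rna
  attr(out, "gates") <- list()
  class(out) <- c("cell_table", class(out))
  out
}

#' Gate specification
#'
#' A conjunction (AND) of per-channel threshold rules defining a phenotype,
#' e.g. "CAR+ GZMB+" as `CAR >= 3 AND GZMB >= 3`.
#'
#' @param label Phenotype label.
#' @param roles Character vector of table columns.
#' @param thresholds Numeric thresholds (finite), one per role.
#' @param directions `">="` or `"<"` per role (recycled).
#' @return A `gate_spec`.
#' @examples
#' gate_spec("CAR+", "CAR", 3)
#' gate_spec("CAR+GZMB-", c("CAR", "GZMB"), c(3, 3), c(">=", "<"))
#' @export
gate_spec <- function(label, roles, thresholds, directions = ">=") {
  if (any(!is.finite(thresholds))) abort("thresholds must be finite")
  directions <- rep(directions, length.out = length(roles))
  if (!all(directions %in% c(">=", "<"))) {
    abort('directions must be ">=" or "<"')
  }
  structure(list(label = label,
                 rules = tibble(role = roles, threshold = thresholds,
                                direction = directions)),
            class = "gate_spec")
}

#' Apply a gate to a cell table
#'
#' @param table A `cell_table`.
#' @param spec A [gate_spec()].
#' @return A `gate_result`: `membership` tibble (`cell_id`, `positive`),
#'   `n_pos`, `n_total`, `fraction` (NA with `undefined = TRUE` on an empty
#'   table), and the spec.
#' @export
gate_cells <- function(table, spec) {
  stopifnot(inherits(spec, "gate_spec"))
  missing_roles <- setdiff(spec$rules$role, names(table))
  if (length(missing_roles)) {
    abort(paste0("gate role not in table: ", missing_roles[1]))
  }
  if (!nrow(table)) {
    return(structure(list(membership = tibble(cell_id = integer(),
                                              positive = logical()),
                          n_pos = 0L, n_total = 0L, fraction = NA_real_,
                          undefined = TRUE, spec = spec),
                     class = "gate_result"))
  }
  pos <- rep(TRUE, nrow(table))
  for (k in seq_len(nrow(spec$rules))) {
    v <- table[[spec$rules$role[k]]]
    pos <- pos & if (spec$rules$direction[k] == ">=") {
      v >= spec$rules$threshold[k]
    } else {
      v < spec$rules$threshold[k]
    }
  }
  structure(list(membership = tibble(cell_id = table$cell_id, positive = pos),
                 n_pos = sum(pos), n_total = nrow(table),
                 fraction = mean(pos), undefined = FALSE, spec = spec),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %s: %d / %d positive (%.2f%%)\n",
              x$spec$label, x$n_pos, x$n_total, 100 * x$fraction))
  invisible(x)
}

#' Automatic IHC positivity gate
#'
#' Chooses the per-section IHC threshold minimising intra-class variance
#' (Otsu's criterion) over the table's `ihc` column.
#'
#' @param table A `cell_table`.
#' @param label Gate label.
#' @return A [gate_spec()] on `ihc`.
#' @export
ihc_gate <- function(table, label = "IHC+") {
  gate_spec(label, "ihc", otsu_threshold(table$ihc))
}

#' Expected marker-positive fraction of a dilution point
#'
#' A stock of flow-cytometric purity `purity` mixed into negative cells at
#' `ratio` is expected to yield `100 * purity * ratio` percent positive
#' cells: 90%, 67.5%, 45%, 22.5% and 0% for purity 0.90 at ratios 1, 0.75,
#' 0.5, 0.25 and 0.
#'
#' @param purity,ratio Fractions in \[0, 1\].
#' @return Expected positive percentage.
#' @examples
#' expected_positive_fraction(0.90, 0.75)  # 67.5
#' @export
expected_positive_fraction <- function(purity, ratio) {
  if (any(purity < 0 | purity > 1) || any(ratio < 0 | ratio > 1)) {
    abort("purity and ratio must be in [0, 1]")
  }
  100 * purity * ratio
}

#' Ordinary least squares of observed on expected dilution fractions
#'
#' The dilution-series validation statistic: regress the recovered
#' positive-cell fractions on the expected fractions and report slope,
#' intercept and R^2 (`1 - SS_res / SS_tot`).
#'
#' @param observed,expected Equal-length numeric vectors (>= 3 points);
#'   `expected` must have positive variance.
#' @return A `dilution_fit`: `slope`, `intercept`, `r_squared`, the
#'   underlying `lm`, and the data. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
dilution_fit <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 3) {
    abort("observed and expected must have equal length >= 3")
  }
  if (sd(expected) == 0) abort("expected values have zero variance")
  d <- tibble(observed = observed, expected = expected)
  m <- lm(observed ~ expected, data = d)
  # summary.lm warns on an exactly collinear ("perfect") fit; R^2 is fine
  r2 <- suppressWarnings(summary(m)$r.squared)
  structure(list(slope = unname(coef(m)[2]),
                 intercept = unname(coef(m)[1]),
                 r_squared = r2,
                 model = m, data = d),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(
    "<dilution_fit> observed = %.3f * expected + %.3f, R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.dilution_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.dilution_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = nrow(x$data))
}
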