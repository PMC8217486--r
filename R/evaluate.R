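# Recovery evaluation against synthetic ground truth.

# IoU of two polygons (um coords) by rasterisation on their joint bbox.
polygon_iou <- function(pa, pb, grid_um = 0.5) {
  x0 <- min(pa[, 1], pb[, 1]); x1 <- max(pa[, 1], pb[, 1])
  y0 <- min(pa[, 2], pb[, 2]); y1 <- max(pa[, 2], pb[, 2])
  xs <- seq(x0, x1, by = grid_um); ys <- seq(y0, y1, by = grid_um)
  g <- expand.grid(x = xs, y = ys)
  ina <- points_in_polygon(g$x, g$y, pa)
  inb <- points_in_polygon(g$x, g$y, pb)
  u <- sum(ina | inb)
  if (u == 0) return(0)
  sum(ina & inb) / u
}

#' Match segmented cells to ground-truth cells
#'
#' Greedy one-to-one matching by intersection-over-union: each ground-truth
#' cell is paired with the unmatched segmented cell of highest IoU at or
#' above `iou_min`.
#'
#' @param table A `cell_table` with a `polygon` list-column (global um).
#' @param gt A `ground_truth`.
#' @param iou_min Minimum IoU to accept a match.
#' @param grid_um Rasterisation grid for the IoU computation.
#' @return A list: `matches` tibble (`gt_id`, `cell_id`, `iou`),
#'   `n_matched`, `n_missed` (unmatched truth), `n_false` (unmatched
#'   segmented cells).
#' @export
match_cells <- function(table, gt, iou_min = 0.5, grid_um = 0.5) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!"polygon" %in% names(table)) {
    abort("table must carry the polygon list-column to be matched")
  }
  used <- logical(nrow(table))
  rows <- list()
  for (i in seq_len(nrow(gt$cells))) {
    gp <- gt$cells$polygon[[i]]
    cx <- gt$cells$x_um[i]; cy <- gt$cells$y_um[i]
    rr <- gt$cells$radius_um[i]
    cand <- which(!used &
                    abs(table$x_um - cx) < 2.5 * rr &
                    abs(table$y_um - cy) < 2.5 * rr)
    if (!length(cand)) next
    ious <- map_dbl(cand, function(j)
      polygon_iou(gp, table$polygon[[j]], grid_um))
    best <- which.max(ious)
    if (ious[best] >= iou_min) {
      used[cand[best]] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        gt_id = gt$cells$cell_id[i],
        cell_id = table$cell_id[cand[best]],
        iou = ious[best])
    }
  }
  matches <- if (length(rows)) bind_rows(rows) else
    tibble(gt_id = integer(), cell_id = integer(), iou = double())
  list(matches = matches,
       n_matched = nrow(matches),
       n_missed = nrow(gt$cells) - nrow(matches),
       n_false = nrow(table) - nrow(matches))
}
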