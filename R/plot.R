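# ggplot2 figures for the main result types.

#' Plot a cell table as an x-y event map
#'
#' Scatter of cell centroids over the section, optionally coloured by a
#' gated phenotype column or any table column.
#'
#' @param object A `cell_table`.
#' @param colour_by Optional column name to colour points by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_table <- function(object, colour_by = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$x_um, y = .data$y_um))
  if (!is.null(colour_by)) {
    p <- p + geom_point(aes(colour = .data[[colour_by]]), size = 0.4)
  } else {
    p <- p + geom_point(size = 0.4, alpha = 0.6)
  }
  p + ggplot2::scale_y_reverse() + coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") + theme_minimal()
}

#' Plot a tissue partition with its cells
#'
#' High-region contours over the cell map, cells coloured by region.
#'
#' @param object An `area_partition`.
#' @param table The `cell_table` the partition was built from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.area_partition <- function(object, table, ...) {
  cells <- as_tibble(table)
  cells$region <- object$assignment$region[
    match(cells$cell_id, object$assignment$cell_id)]
  polys <- bind_rows(imap(object$high_polys, function(p, i)
    tibble(x = p$x, y = p$y, contour = i)))
  p <- ggplot(cells, aes(x = .data$x_um, y = .data$y_um)) +
    geom_point(aes(colour = .data$region), size = 0.4)
  if (nrow(polys)) {
    p <- p + geom_polygon(data = polys,
                          aes(x = .data$x, y = .data$y,
                              group = .data$contour),
                          fill = NA, colour = "goldenrod", linewidth = 0.6)
  }
  p + ggplot2::scale_y_reverse() + coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "region") +
    theme_minimal()
}

#' Plot a dilution fit
#'
#' Observed vs expected positive fractions with the fitted line and the
#' identity for reference.
#'
#' @param object A `dilution_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dilution_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    geom_point(size = 2) +
    labs(x = "expected positive fraction",
         y = "observed positive fraction",
         subtitle = sprintf("slope %.3f, R² = %.3f",
                            object$slope, object$r_squared)) +
    theme_minimal()
}
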