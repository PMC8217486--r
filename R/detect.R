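# Laplacian-of-Gaussian detection of nuclei, FISH dots and IHC signal,
# and assignment of detections to segmented cell loops.

#' Detection parameters
#'
#' @param spot_sigma_px LoG sigma for sub-resolution FISH dots (px);
#'   a sensible default is 0.6 um divided by the pixel size.
#' @param nucleus_sigma_px LoG sigma for nuclei; default scale 3 um.
#' @param min_prominence Minimum LoG response; `NULL` selects
#'   5x the robust noise SD (median absolute deviation) of the response.
#' @param min_separation_px No two detections closer than this (>= 1);
#'   the higher response wins, ties by lower (y, x).
#' @return A `detect_params` object.
#' @export
detect_params <- function(spot_sigma_px = 1.2, nucleus_sigma_px = 6,
                          min_prominence = NULL, min_separation_px = 2) {
  if (spot_sigma_px <= 0 || nucleus_sigma_px <= 0) abort("sigmas must be > 0")
  if (min_separation_px < 1) abort("min_separation_px must be >= 1")
  structure(as.list(environment()), class = "detect_params")
}

# Scale-normalised negative-LoG filter response (bright blobs positive).
log_response <- function(channel, sigma) {
  r <- max(2L, ceiling(4 * sigma))
  ax <- -r:r
  g <- exp(-ax^2 / (2 * sigma^2))
  g <- g / sum(g)
  # LoG kernel = separable second-derivative combination
  gxx <- (ax^2 / sigma^4 - 1 / sigma^2) * g
  k <- outer(gxx, g) + outer(g, gxx)
  k <- k - mean(k)  # zero-sum: constant images give zero response
  resp <- EBImage::filter2(channel, -sigma^2 * k, boundary = "replicate")
  matrix(resp, nrow(channel), ncol(channel))
}

#' Detect blob-like local maxima with a Laplacian of Gaussian
#'
#' Points are local maxima of the scale-normalised negative-LoG response at
#' `sigma_px`, above `min_prominence`, greedily thinned so no two survive
#' within `min_separation_px` (higher response wins; ties resolved toward
#' lower (y, x)). Detections outside the analysis mask are discarded.
#'
#' @param channel 2-D intensity matrix.
#' @param sigma_px Blob scale in pixels.
#' @param min_prominence Response threshold; `NULL` = 5x MAD of the masked
#'   response.
#' @param min_separation_px Greedy thinning radius.
#' @param mask Optional logical analysis mask.
#' @return A `spot_set`: tibble with 0-based `x`, `y` and `response`,
#'   carrying `sigma_px` and the realised `min_prominence` as attributes.
#' @export
log_maxima <- function(channel, sigma_px, min_prominence = NULL,
                       min_separation_px = 2, mask = NULL) {
  if (any(!is.finite(channel))) abort("channel must be finite")
  h <- nrow(channel); w <- ncol(channel)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  resp <- log_response(channel, sigma_px)
  if (is.null(min_prominence)) {
    # 5x robust noise SD, floored at 2% of the peak response and at the
    # FFT round-off scale, so numerically tiny ripple cannot pass on
    # (near-)noiseless images
    min_prominence <- max(5 * mad(resp[mask]),
                          0.02 * max(resp[mask], 0),
                          1e-6 * max(abs(channel)), 1e-12)
  }
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- resp
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & resp >= pad[(2 + dy):(h + 1 + dy),
                                   (2 + dx):(w + 1 + dx)]
  }
  cand <- which(is_max & mask & resp > min_prominence)
  out <- tibble(x = integer(), y = integer(), response = double())
  if (length(cand)) {
    cy <- (cand - 1L) %% h
    cx <- (cand - 1L) %/% h
    rv <- resp[cand]
    ord <- order(-rv, cy, cx)  # response desc, ties by lower (y, x)
    cx <- cx[ord]; cy <- cy[ord]; rv <- rv[ord]
    keep <- logical(length(cand))
    min_sep2 <- min_separation_px^2
    kept_x <- double(0); kept_y <- double(0)
    for (i in seq_along(cand)) {
      if (!length(kept_x) ||
          all((kept_x - cx[i])^2 + (kept_y - cy[i])^2 >= min_sep2)) {
        keep[i] <- TRUE
        kept_x <- c(kept_x, cx[i]); kept_y <- c(kept_y, cy[i])
      }
    }
    out <- tibble(x = cx[keep], y = cy[keep], response = rv[keep])
  }
  attr(out, "sigma_px") <- sigma_px
  attr(out, "min_prominence") <- min_prominence
  class(out) <- c("spot_set", class(out))
  out
}

# Rasterise loops into a label image; errors if two loops claim more than
# `tol` of the smaller loop's pixels (overlap violates the segmentation
# guarantee).
loops_label_image <- function(loops, shape, tol = 0.1) {
  labim <- matrix(0L, shape[1], shape[2])
  areas <- double(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    px <- loops$pixels[[i]]
    areas[i] <- nrow(px)
    prev <- labim[px]
    clash <- prev > 0L
    if (any(clash)) {
      for (j in unique(prev[clash])) {
        n_over <- sum(prev == j)
        if (n_over > tol * min(areas[i], areas[j])) {
          abort("overlapping cell loops: segmentation invariant violated")
        }
      }
    }
    labim[px] <- loops$loop_id[i]
  }
  labim
}

#' Assign detected points to cell loops
#'
#' Point-in-polygon assignment by the even-odd rule with a half-open
#' boundary convention (each point lands in at most one loop). Points inside
#' no loop are reported as unassigned, never attributed. Loops overlapping
#' by more than 10% of the smaller area raise an error.
#'
#' @param spots A `spot_set` (or tibble with `x`, `y`).
#' @param loops A `cell_loops` tibble from [extract_loops()].
#' @param boundary_tol_px Points up to this distance outside a loop's
#'   contour are still attributed to it (the contour runs through the
#'   region's boundary-pixel centres, about half the membrane band inside
#'   the ridge midline; a dot under the membrane belongs to the cell on
#'   whose side it sits). At most half the membrane-band width is safe.
#' @return A list: `counts` tibble (`loop_id`, `n`), `assignment` (integer
#'   loop id per spot, 0 = unassigned), `n_unassigned`.
#' @export
assign_points_to_cells <- function(spots, loops, boundary_tol_px = 1.5) {
  if (nrow(loops)) {
    shape <- c(max(map_dbl(loops$pixels, ~max(.x[, 1]))),
               max(map_dbl(loops$pixels, ~max(.x[, 2]))))
    loops_label_image(loops, shape)  # errors on >10% overlap
  }
  assign <- integer(nrow(spots))
  for (i in seq_len(nrow(loops))) {
    poly <- loops$polygon[[i]]
    bb <- assign == 0L &
      spots$x >= min(poly[, 1]) - 1 & spots$x <= max(poly[, 1]) + 1 &
      spots$y >= min(poly[, 2]) - 1 & spots$y <= max(poly[, 2]) + 1
    if (!any(bb)) next
    inside <- points_in_polygon(spots$x[bb], spots$y[bb], poly)
    assign[which(bb)[inside]] <- loops$loop_id[i]
  }
  # points on or just outside a contour (the contour runs through
  # boundary-pixel centres, inside the membrane midline) belong to that
  # loop; the even-odd test treats them as outside. Nearest loop wins.
  pending <- which(assign == 0L)
  if (length(pending) && nrow(loops)) {
    best_d <- rep(Inf, length(pending))
    best_id <- integer(length(pending))
    for (i in seq_len(nrow(loops))) {
      poly <- loops$polygon[[i]]
      bb <- spots$x[pending] >= min(poly[, 1]) - boundary_tol_px &
        spots$x[pending] <= max(poly[, 1]) + boundary_tol_px &
        spots$y[pending] >= min(poly[, 2]) - boundary_tol_px &
        spots$y[pending] <= max(poly[, 2]) + boundary_tol_px
      if (!any(bb)) next
      d <- dist_to_segments(spots$x[pending[bb]], spots$y[pending[bb]], poly)
      upd <- d < best_d[bb]
      best_d[bb][upd] <- d[upd]
      best_id[bb][upd] <- loops$loop_id[i]
    }
    hit <- best_d <= boundary_tol_px
    assign[pending[hit]] <- best_id[hit]
  }
  counts <- tibble(loop_id = loops$loop_id,
                   n = map_int(loops$loop_id,
                               ~sum(assign == .x)))
  list(counts = counts, assignment = assign,
       n_unassigned = sum(assign == 0L))
}

#' Mean interior IHC intensity per cell loop
#'
#' Averages the channel over each loop's interior pixels (region pixels not
#' on the region boundary), after subtracting the channel's masked median
#' as background. Diffuse IHC stains are summarised by mean intensity, not
#' by maxima counts; a maxima-count mode is available via [log_maxima()] on
#' the IHC channel for strict fidelity to dot-like readouts.
#'
#' @param channel 2-D intensity matrix.
#' @param loops A `cell_loops` tibble.
#' @param mask Optional logical mask for the background median.
#' @return Tibble `loop_id`, `ihc` (background-subtracted mean).
#' @export
measure_ihc <- function(channel, loops, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel), ncol(channel))
  bg <- median(channel[mask])
  vals <- map_dbl(seq_len(nrow(loops)), function(i) {
    px <- loops$pixels[[i]][loops$interior[[i]], , drop = FALSE]
    if (!nrow(px)) {
      warn(sprintf("loop %d has no interior pixels; intensity 0",
                   loops$loop_id[i]))
      return(0)
    }
    mean(channel[px]) - bg
  })
  tibble(loop_id = loops$loop_id, ihc = vals)
}
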