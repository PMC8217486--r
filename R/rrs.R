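# Random-reaction-seed membrane tracing.
#
# Seeds are scattered on bright membrane pixels; each seed launches a
# bidirectional walker over quantised headings. The walker is a first-order
# Markov chain whose states are headings, whose emissions are the local
# ridge contrast (log ratio of membrane intensity to a smoothed local
# background), and whose transitions penalise turning; decoding is greedy
# per-step maximum likelihood. Walks that return to their origin close a
# loop — a cell. Accepted traces are rasterised into a net-like draft of
# the membrane map; enclosed regions of the draft that pass area and
# boundary-coverage filters become cell loops, which removes false-positive
# membranes.

#' Tracing parameters
#'
#' @param n_seeds Seeds per tile ("several thousand" is the working regime;
#'   the default is 4000 for a full tile).
#' @param seed_intensity_percentile Seeds are drawn only from masked pixels
#'   at or above this membrane-intensity percentile.
#' @param n_directions Number of quantised headings (>= 8).
#' @param step_px Step length in pixels (0 < step <= 3).
#' @param turn_penalty Log-likelihood penalty per radian of turning.
#' @param intensity_weight Weight of the log intensity-ratio emission term.
#' @param max_steps Maximum steps per walk direction.
#' @param closure_radius_px A walk closes when it returns within this
#'   distance of its origin (>= 1).
#' @param min_perimeter_px Minimum path length before closure is allowed.
#' @param score_floor A walk stops when its best per-step score drops below
#'   this floor.
#' @param bg_sigma_px Gaussian sigma of the local-background estimate.
#' @param net_accept_loglik Open traces enter the net only if their mean
#'   per-step score is at least this value.
#' @param net_support_nmad Trace pixels enter the net only where the
#'   membrane intensity exceeds the masked median by this many robust noise
#'   SDs (median absolute deviations); suppresses walls traced across dim
#'   background between cells.
#' @return An `rrs_params` object.
#' @export
rrs_params <- function(n_seeds = 4000L, seed_intensity_percentile = 80,
                       n_directions = 16L, step_px = 1.5,
                       turn_penalty = 0.3, intensity_weight = 2.0,
                       max_steps = 600L, closure_radius_px = 3,
                       min_perimeter_px = 20, score_floor = 0,
                       bg_sigma_px = 8, net_accept_loglik = 0.2,
                       net_support_nmad = 5) {
  if (n_seeds < 1) abort("n_seeds must be >= 1")
  if (n_directions < 8) abort("n_directions must be >= 8")
  if (!(step_px > 0 && step_px <= 3)) abort("step_px must be in (0, 3]")
  if (closure_radius_px < 1) abort("closure_radius_px must be >= 1")
  structure(as.list(environment()), class = "rrs_params")
}

#' Scatter reaction seeds on bright membrane pixels
#'
#' Draws `n_seeds` pixel positions uniformly without replacement from the
#' masked pixels whose intensity reaches the configured percentile. If fewer
#' pixels qualify, all of them are returned with a warning.
#'
#' @param membrane 2-D membrane-channel matrix.
#' @param mask Logical analysis mask (same shape), or `NULL` for all pixels.
#' @param params An [rrs_params()].
#' @param rng_seed Integer seed.
#' @return Tibble with 0-based pixel columns `x`, `y`.
#' @export
sample_seeds <- function(membrane, mask = NULL, params = rrs_params(),
                         rng_seed = 1L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(membrane), ncol(membrane))
  vals <- membrane[mask]
  if (!length(vals) || diff(range(vals)) == 0) {
    warn("membrane is constant within the mask; no eligible seed pixels")
    return(tibble(x = integer(), y = integer()))
  }
  thr <- quantile(vals, params$seed_intensity_percentile / 100, names = FALSE)
  elig <- which(mask & membrane >= thr)
  n <- min(params$n_seeds, length(elig))
  if (length(elig) < params$n_seeds) {
    warn(sprintf("only %d eligible pixels for %d seeds; returning all",
                 length(elig), params$n_seeds))
  }
  pick <- with_rng(rng_seed, sample(elig, n))
  h <- nrow(membrane)
  tibble(x = (pick - 1L) %/% h, y = (pick - 1L) %% h)
}

# Smoothed local background used in the emission term.
local_background <- function(membrane, sigma) {
  b <- EBImage::gblur(membrane, sigma = sigma)
  pmax(matrix(b, nrow(membrane), ncol(membrane)), 1e-6)
}

# Vectorised walker engine. Runs all walkers simultaneously; greedy
# maximum-likelihood step over candidate headings (current +/- 2 direction
# quanta). Returns per-walker paths, scores and termination status.
run_walkers <- function(membrane, bg, mask, sx, sy, dir0, target_x, target_y,
                        len_offset, params) {
  n <- length(sx)
  D <- params$n_directions
  step <- params$step_px
  eps <- 1e-6
  theta <- 2 * pi * (0:(D - 1)) / D
  deltas <- -2:2
  dpen <- params$turn_penalty * abs(deltas) * (2 * pi / D)

  X <- matrix(NA_real_, params$max_steps + 1L, n)
  Y <- matrix(NA_real_, params$max_steps + 1L, n)
  S <- matrix(NA_real_, params$max_steps, n)
  X[1, ] <- sx; Y[1, ] <- sy
  px <- sx; py <- sy
  dir <- dir0
  plen <- rep(0, n)
  nst <- rep(0L, n)
  status <- rep(0L, n)          # 0 active 1 closed 2 floor 3 mask 4 maxsteps
  act <- which(status == 0L)
  h <- nrow(membrane); w <- ncol(membrane)

  for (stp in seq_len(params$max_steps)) {
    if (!length(act)) break
    na <- length(act)
    cand_dir <- (rep(dir[act], times = 5) +
                   rep(deltas, each = na)) %% D
    nx <- rep(px[act], 5) + step * cos(theta[cand_dir + 1])
    ny <- rep(py[act], 5) + step * sin(theta[cand_dir + 1])
    inb <- nx >= 0 & ny >= 0 & nx <= w - 1 & ny <= h - 1
    inm <- inb
    if (any(inb)) {
      mi <- cbind(pmin(pmax(round(ny[inb]), 0), h - 1) + 1,
                  pmin(pmax(round(nx[inb]), 0), w - 1) + 1)
      inm[inb] <- mask[mi]
    }
    I <- pmax(bilinear(membrane, nx, ny, fill = 0), 0)
    B <- pmax(bilinear(bg, nx, ny, fill = 1), eps)
    sc <- params$intensity_weight * log((I + eps) / (B + eps)) -
      rep(dpen, each = na)
    sc[!inm] <- -Inf
    scm <- matrix(sc, na, 5)
    best <- max.col(scm, ties.method = "first")
    bsc <- scm[cbind(seq_len(na), best)]

    left <- !is.finite(bsc)
    floored <- is.finite(bsc) & bsc <= params$score_floor
    move <- !(left | floored)
    status[act[left]] <- 3L
    status[act[floored]] <- 2L

    if (any(move)) {
      am <- act[move]
      pick <- (best[move] - 1) * na + seq_len(na)[move]
      px[am] <- nx[pick]; py[am] <- ny[pick]
      dir[am] <- cand_dir[pick]
      plen[am] <- plen[am] + step
      nst[am] <- nst[am] + 1L
      X[cbind(nst[am] + 1L, am)] <- px[am]
      Y[cbind(nst[am] + 1L, am)] <- py[am]
      S[cbind(nst[am], am)] <- bsc[move]
      dclose <- sqrt((px[am] - target_x[am])^2 + (py[am] - target_y[am])^2)
      closed <- plen[am] + len_offset[am] >= params$min_perimeter_px &
        dclose <= params$closure_radius_px
      status[am[closed]] <- 1L
      status[am[nst[am] >= params$max_steps & status[am] == 0L]] <- 4L
    }
    act <- which(status == 0L)
  }
  list(X = X, Y = Y, S = S, n_steps = nst, status = status,
       path_len = plen, end_x = px, end_y = py, end_dir = dir)
}

# Best initial heading at each seed (greedy over all D directions).
initial_headings <- function(membrane, bg, mask, sx, sy, params) {
  D <- params$n_directions
  theta <- 2 * pi * (0:(D - 1)) / D
  n <- length(sx)
  h <- nrow(membrane); w <- ncol(membrane)
  eps <- 1e-6
  nx <- rep(sx, D) + params$step_px * rep(cos(theta), each = n)
  ny <- rep(sy, D) + params$step_px * rep(sin(theta), each = n)
  I <- pmax(bilinear(membrane, nx, ny, fill = 0), 0)
  B <- pmax(bilinear(bg, nx, ny, fill = 1), eps)
  inb <- nx >= 0 & ny >= 0 & nx <= w - 1 & ny <= h - 1
  inm <- inb
  if (any(inb)) {
    mi <- cbind(pmin(pmax(round(ny[inb]), 0), h - 1) + 1,
                pmin(pmax(round(nx[inb]), 0), w - 1) + 1)
    inm[inb] <- mask[mi]
  }
  sc <- params$intensity_weight * log((I + eps) / (B + eps))
  sc[!inm] <- -Inf
  scm <- matrix(sc, n, D)
  best <- max.col(scm, ties.method = "first")
  list(dir = best - 1L, score = scm[cbind(seq_len(n), best)])
}

# Trace every seed bidirectionally; returns a list of trace_path objects.
trace_all <- function(membrane, seeds, params, mask = NULL, bg = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(membrane), ncol(membrane))
  if (is.null(bg)) bg <- local_background(membrane, params$bg_sigma_px)
  n <- nrow(seeds)
  if (!n) return(list())
  sx <- as.numeric(seeds$x); sy <- as.numeric(seeds$y)
  init <- initial_headings(membrane, bg, mask, sx, sy, params)
  dead <- init$score <= params$score_floor | !is.finite(init$score)

  f <- run_walkers(membrane, bg, mask, sx, sy, init$dir, sx, sy,
                   rep(0, n), params)
  # second walk in the opposite heading for paths that did not close;
  # closure target is the forward walk's endpoint
  need_back <- f$status != 1L & !dead
  D <- params$n_directions
  b <- run_walkers(membrane, bg, mask, sx[need_back], sy[need_back],
                   (init$dir[need_back] + D %/% 2L) %% D,
                   f$end_x[need_back], f$end_y[need_back],
                   f$path_len[need_back], params)
  bidx <- integer(n); bidx[need_back] <- seq_len(sum(need_back))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (dead[i]) {
      out[[i]] <- new_trace_path(cbind(x = sx[i], y = sy[i]), numeric(0),
                                 FALSE, params)
      next
    }
    kf <- f$n_steps[i]
    fx <- f$X[seq_len(kf + 1L), i]; fy <- f$Y[seq_len(kf + 1L), i]
    fs <- if (kf) f$S[seq_len(kf), i] else numeric(0)
    if (f$status[i] == 1L) {
      out[[i]] <- new_trace_path(cbind(x = fx, y = fy), fs, TRUE, params)
    } else {
      j <- bidx[i]
      kb <- b$n_steps[j]
      if (kb) {
        bx <- rev(b$X[seq_len(kb + 1L), j]); by <- rev(b$Y[seq_len(kb + 1L), j])
        bs <- rev(b$S[seq_len(kb), j])
        pts <- cbind(x = c(bx, fx[-1]), y = c(by, fy[-1]))
        out[[i]] <- new_trace_path(pts, c(bs, fs), b$status[j] == 1L, params)
      } else {
        out[[i]] <- new_trace_path(cbind(x = fx, y = fy), fs, FALSE, params)
      }
    }
  }
  out
}

new_trace_path <- function(points, step_loglik, closed, params) {
  structure(list(points = points, step_loglik = step_loglik,
                 closed = closed,
                 length_px = params$step_px * length(step_loglik)),
            class = "trace_path")
}

#' @export
print.trace_path <- function(x, ...) {
  cat(sprintf("<trace_path> %d points, %s, mean loglik %.3f\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              if (length(x$step_loglik)) mean(x$step_loglik) else NA))
  invisible(x)
}

#' Trace the membrane from one seed
#'
#' Launches a greedy maximum-likelihood walk over quantised headings in the
#' best initial direction and, if it does not close, a second walk in the
#' opposite direction; the two halves are concatenated. The per-step score
#' is `intensity_weight * log(I_next / I_background) - turn_penalty *
#' |dtheta|`. The walk terminates on loop closure, on leaving the mask, when
#' the best score falls below `score_floor`, or at `max_steps`.
#'
#' @param membrane 2-D membrane matrix.
#' @param seed `(x, y)` pixel position (0-based).
#' @param params An [rrs_params()].
#' @param mask Optional logical analysis mask.
#' @return A `trace_path`: `points` (n x 2), `step_loglik`, `closed`.
#' @export
trace_from_seed <- function(membrane, seed, params = rrs_params(),
                            mask = NULL) {
  trace_all(membrane, tibble(x = seed[1], y = seed[2]), params, mask)[[1]]
}

#' Build the net-like membrane draft from traces
#'
#' Closed traces, and open traces whose mean per-step score clears
#' `net_accept_loglik`, are rasterised (with midpoint filling so unit steps
#' leave no gaps), thickened by one pixel and skeletonised to a 1-px-wide
#' net.
#'
#' @param traces List of `trace_path`s.
#' @param shape `c(n_row, n_col)` of the tile.
#' @param params An [rrs_params()].
#' @param membrane Optional membrane image: net pixels are additionally
#'   required to sit on intensities above the masked median plus
#'   `net_support_nmad` robust noise SDs (walls traced across dim
#'   background between cells are discarded — part of false-membrane
#'   removal).
#' @param mask Optional analysis mask for the support percentile.
#' @return A `membrane_net`: logical `raster` plus the accepted trace count.
#' @export
build_net <- function(traces, shape, params = rrs_params(),
                      membrane = NULL, mask = NULL) {
  raster <- matrix(FALSE, shape[1], shape[2])
  n_acc <- 0L
  for (tr in traces) {
    if (nrow(tr$points) < 3) next
    ok <- tr$closed ||
      (length(tr$step_loglik) >= 5 &&
         mean(tr$step_loglik) >= params$net_accept_loglik)
    if (!ok) next
    n_acc <- n_acc + 1L
    p <- tr$points
    if (tr$closed) p <- rbind(p, p[1, ])
    mx <- (p[-1, 1] + p[-nrow(p), 1]) / 2
    my <- (p[-1, 2] + p[-nrow(p), 2]) / 2
    xs <- round(c(p[, 1], mx)); ys <- round(c(p[, 2], my))
    keep <- xs >= 0 & ys >= 0 & xs < shape[2] & ys < shape[1]
    raster[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  }
  if (!is.null(membrane) && any(raster)) {
    if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
    v <- membrane[mask]
    thr <- median(v) + params$net_support_nmad * mad(v)
    raster <- raster & membrane >= thr
  }
  if (any(raster)) raster <- thin_raster(dilate3(raster))
  structure(list(raster = raster, n_accepted = n_acc),
            class = "membrane_net")
}

#' @export
print.membrane_net <- function(x, ...) {
  cat(sprintf("<membrane_net> %d x %d, %d net px from %d traces\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster), x$n_accepted))
  invisible(x)
}

#' Segment cell loops from the membrane net
#'
#' Connected background regions fully enclosed by net pixels (4-connected
#' background against the 8-connected net curve) become loop candidates.
#' Candidates touching the image border, outside the area bounds, or whose
#' boundary has less than `coverage_min` of its length adjacent to net
#' pixels are rejected — this is the false-membrane removal step. Areas are
#' pixel counts plus half the boundary (the membrane midline splits the
#' boundary pixel between neighbours). Polygons are traced
#' counter-clockwise (positive shoelace area in the x-right/y-down pixel
#' frame).
#'
#' @param net A `membrane_net` (or logical raster).
#' @param area_bounds_px2 `c(min, max)` accepted loop area in px^2.
#' @param coverage_min Minimum boundary coverage fraction in `[0, 1]`.
#' @return A tibble of class `cell_loops`: `loop_id`, `polygon` (list of
#'   0-based px vertex matrices), `area_px2`, `centroid_x`, `centroid_y`,
#'   `coverage`, `pixels` (list of (row, col) 1-based index matrices),
#'   `interior` (list of logical vectors: pixel not on region boundary).
#' @export
extract_loops <- function(net, area_bounds_px2, coverage_min = 0.8) {
  raster <- if (inherits(net, "membrane_net")) net$raster else net
  h <- nrow(raster); w <- ncol(raster)
  lab <- label_regions4(!raster)
  nlab <- max(lab)
  empty <- tibble(loop_id = integer(), polygon = list(),
                  area_px2 = double(), centroid_x = double(),
                  centroid_y = double(), coverage = double(),
                  pixels = list(), interior = list())
  class(empty) <- c("cell_loops", class(empty))
  if (nlab == 0) return(empty)
  # quickly reject labels touching the border or with absurd size
  sizes <- tabulate(lab, nlab)
  border_labs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  cand <- which(sizes >= max(1, area_bounds_px2[1] * 0.5) &
                  sizes <= area_bounds_px2[2] * 1.5)
  cand <- setdiff(cand, border_labs[border_labs > 0])
  rows <- list()
  pad <- function(m) {
    o <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    o[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    o
  }
  for (lb in cand) {
    idx <- which(lab == lb)
    ry <- (idx - 1L) %% h + 1L
    rx <- (idx - 1L) %/% h + 1L
    y0 <- min(ry); y1 <- max(ry); x0 <- min(rx); x1 <- max(rx)
    sub <- lab[y0:y1, x0:x1, drop = FALSE] == lb
    ps <- pad(sub)
    hh <- nrow(sub); ww <- ncol(sub)
    nb4 <- ps[1:hh, 2:(ww + 1)] & ps[3:(hh + 2), 2:(ww + 1)] &
      ps[2:(hh + 1), 1:ww] & ps[2:(hh + 1), 3:(ww + 2)]
    boundary <- sub & !nb4
    # coverage: boundary pixels with a net pixel among their 8 neighbours
    y0e <- max(1, y0 - 1); x0e <- max(1, x0 - 1)
    nn <- dilate3(raster[y0e:min(h, y1 + 1), x0e:min(w, x1 + 1),
                         drop = FALSE])
    near_net <- nn[(y0 - y0e + 1):(y0 - y0e + hh),
                   (x0 - x0e + 1):(x0 - x0e + ww), drop = FALSE]
    nb <- sum(boundary)
    cov <- if (nb) sum(boundary & near_net) / nb else 0
    area <- sum(sub) + nb / 2
    if (area < area_bounds_px2[1] || area > area_bounds_px2[2]) next
    if (cov < coverage_min) next
    # contour polygon (0-based full-image px coords), counter-clockwise
    oc <- EBImage::ocontour(t(sub) * 1)[[1]]
    poly <- cbind(x = oc[, 1] + x0 - 1, y = oc[, 2] + y0 - 1)
    if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    rows[[length(rows) + 1L]] <- tibble(
      polygon = list(poly),
      area_px2 = area,
      centroid_x = mean(rx) - 1, centroid_y = mean(ry) - 1,
      coverage = cov,
      pixels = list(cbind(row = ry, col = rx)),
      interior = list(nb4[cbind(ry - y0 + 1, rx - x0 + 1)])
    )
  }
  if (!length(rows)) return(empty)
  out <- bind_rows(rows)
  out <- arrange(out, .data$centroid_y, .data$centroid_x)
  out <- mutate(out, loop_id = row_number(), .before = 1)
  class(out) <- c("cell_loops", class(out))
  out
}

#' One-call segmentation of a membrane image
#'
#' Convenience wrapper: seeds, traces, net and loops.
#'
#' @inheritParams sample_seeds
#' @inheritParams extract_loops
#' @param rng_seed Integer seed for seed placement.
#' @return A list with `loops`, `net`, `seeds`, `n_traces_closed`.
#' @export
rrs_segment <- function(membrane, mask = NULL, params = rrs_params(),
                        area_bounds_px2, coverage_min = 0.8, rng_seed = 1L) {
  seeds <- sample_seeds(membrane, mask, params, rng_seed)
  traces <- trace_all(membrane, seeds, params, mask)
  net <- build_net(traces, dim(membrane), params, membrane, mask)
  loops <- extract_loops(net, area_bounds_px2, coverage_min)
  list(loops = loops, net = net, seeds = seeds,
       n_traces_closed = sum(map_lgl(traces, "closed")))
}
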