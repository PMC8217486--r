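# Internal geometry / raster helpers shared across modules.

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched. Every exported function that consumes randomness funnels
# through this with an explicit integer seed.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# Derive a child seed from a master seed and a stream index; stays < 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
}

# Largest-remainder apportionment of n into parts proportional to `frac`.
largest_remainder <- function(n, frac) {
  stopifnot(abs(sum(frac) - 1) <= 1e-9)
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken by first occurrence for determinism
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Shoelace signed area of an Nx2 polygon (closed implicitly).
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[i2]) * cr) / (6 * a), sum((y + y[i2]) * cr) / (6 * a))
}

# Even-odd point-in-polygon test, vectorised over points.
# Half-open convention: a point exactly on a horizontal edge belongs to the
# polygon whose interior is below it (edges [y1, y2) treated half-open).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterise a polygon (pixel-centre sampling) within an image of given dim;
# returns integer matrix indices (1-based) of interior pixels.
rasterize_polygon <- function(poly, nrow_img, ncol_img) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- max(0L, floor(xr[1])):min(ncol_img - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(nrow_img - 1L, ceiling(yr[2]))
  if (!length(xs) || !length(ys)) return(cbind(row = integer(), col = integer()))
  g <- expand.grid(x = xs, y = ys)
  keep <- points_in_polygon(g$x, g$y, poly)
  cbind(row = g$y[keep] + 1L, col = g$x[keep] + 1L)
}

# Distance from points to a polyline's segments (vectorised over points).
dist_to_segments <- function(px, py, poly, closed = TRUE) {
  n <- nrow(poly)
  idx <- if (closed) cbind(seq_len(n), c(seq_len(n)[-1], 1L)) else
    cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(nrow(idx))) {
    x1 <- poly[idx[k, 1], 1]; y1 <- poly[idx[k, 1], 2]
    x2 <- poly[idx[k, 2], 1]; y2 <- poly[idx[k, 2], 2]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
    dd <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

# Bilinear interpolation of image values at fractional (x, y) 0-based
# coordinates; out-of-bounds points return `fill`.
bilinear <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  ok <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 0), w - 1 - 1e-9)
  y <- pmin(pmax(y[ok], 0), h - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[i00 + h] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy +
    img[i00 + h + 1] * fx * fy
  out[ok] <- v
  out
}

# 4-connected labelling of a logical mask via row-run merging (igraph
# components). Deterministic label order: first pixel in column-major order.
label_regions4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  runs <- vector("list", w)
  run_id <- 0L
  run_col <- integer(); run_y0 <- integer(); run_y1 <- integer()
  for (j in seq_len(w)) {
    cm <- mask[, j]
    if (!any(cm)) { runs[[j]] <- integer(0); next }
    r <- rle(cm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    ids <- run_id + seq_along(keep)
    run_id <- run_id + length(keep)
    run_col <- c(run_col, rep(j, length(keep)))
    run_y0 <- c(run_y0, starts[keep]); run_y1 <- c(run_y1, ends[keep])
    runs[[j]] <- ids
  }
  if (run_id == 0L) return(lab)
  # edges between vertically-overlapping runs of adjacent columns
  e_from <- vector("list", w); e_to <- vector("list", w)
  for (j in 2:w) {
    a <- runs[[j - 1L]]; b <- runs[[j]]
    if (!length(a) || !length(b)) next
    ef <- integer(0); et <- integer(0)
    for (ib in b) {
      ov <- a[run_y0[a] <= run_y1[ib] & run_y1[a] >= run_y0[ib]]
      if (length(ov)) { ef <- c(ef, ov); et <- c(et, rep(ib, length(ov))) }
    }
    e_from[[j]] <- ef; e_to[[j]] <- et
  }
  g <- igraph::graph_from_edgelist(cbind(unlist(e_from), unlist(e_to)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, run_id - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel components in order of first run id for determinism
  first <- tapply(seq_len(run_id), comp[seq_len(run_id)], min)
  newlab <- integer(max(comp)); newlab[order(first)] <- seq_along(first)
  for (k in seq_len(run_id)) {
    lab[run_y0[k]:run_y1[k], run_col[k]] <- newlab[comp[k]]
  }
  lab
}

# Zhang-Suen thinning of a logical raster to a 1-px skeleton.
thin_raster <- function(mask) {
  m <- mask
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(M, dy, dx) M[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- pad[2:(h + 1), 2:(w + 1)]
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1); p6 <- shift(pad, 1, 0); p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- P & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- P & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- pad[2:(h + 1), 2:(w + 1)]
        inner[cond] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# Binary dilation with a 3x3 box, `iter` times.
dilate3 <- function(mask, iter = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  m <- mask
  for (i in seq_len(iter)) {
    pad <- matrix(FALSE, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- m
    acc <- matrix(FALSE, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      acc <- acc | pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
    m <- acc
  }
  m
}

# Otsu threshold (minimises intra-class variance) for a numeric vector.
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- x[is.finite(x)]
  if (!length(x) || diff(range(x)) == 0) return(if (length(x)) x[1] else 0)
  br <- seq(min(x), max(x), length.out = n_breaks + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_breaks)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  # the criterion is flat across an empty gap between classes; take the
  # middle of the maximal plateau
  kk <- which(between >= max(between) - 1e-9 * abs(max(between)))
  mean(mids[kk])
}

# Format number compactly for messages.
fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
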