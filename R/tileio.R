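# Tile container, TIFF round-trip and vignetting correction.

CHANNEL_ROLES <- c("nuclei", "membrane", "rna_1", "rna_2", "ihc")

#' One multichannel tile
#'
#' Holds the channel images of a single field of a tile scan, keyed by role
#' (`nuclei`, `membrane`, `rna_1`, `rna_2`, `ihc`; any subset containing
#' `membrane`), plus the pixel size and the tile's grid position in the
#' mosaic. Channel images are square matrices indexed `[y + 1, x + 1]` with
#' finite non-negative intensities.
#'
#' @param channels Named list of equal-sized square numeric matrices.
#' @param pixel_size_um Pixel size in micrometres.
#' @param grid_pos Integer `(row, col)` of the tile in the mosaic, 0-based.
#' @return A `tile_image` object.
#' @export
tile_image <- function(channels, pixel_size_um, grid_pos = c(0L, 0L)) {
  if (!length(channels) || is.null(names(channels))) {
    abort("channels must be a named list")
  }
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad)) abort(paste0("unknown channel role: ", bad[1]))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share one shape")
  d <- dims[[1]]
  if (d[1] != d[2]) abort("tile pages must be square")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort(paste0("channel ", nm, " has non-finite or negative intensities"))
    }
  }
  structure(
    list(channels = channels, side_px = d[1],
         pixel_size_um = pixel_size_um,
         grid_pos = as.integer(grid_pos)),
    class = "tile_image"
  )
}

#' @export
print.tile_image <- function(x, ...) {
  cat(sprintf("<tile_image> %d px, %.4g um/px, grid (%d,%d), channels: %s\n",
              x$side_px, x$pixel_size_um, x$grid_pos[1], x$grid_pos[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write / read a tile as a multi-page TIFF
#'
#' One TIFF page per channel. Integer data up to 65535 are written as 16-bit
#' pages and round-trip exactly; other data are written as 32-bit float
#' pages scaled to `[0, 1]`. Channel roles, per-page intensity scales, pixel
#' size and grid position are stored in a JSON sidecar `<path>.json`, which
#' [read_tile()] consumes (the baseline R TIFF writer does not persist
#' per-page description tags).
#'
#' @param tile A [tile_image()].
#' @param path Output TIFF path.
#' @return `write_tile()` returns `path` invisibly; `read_tile()` returns a
#'   `tile_image`.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "tile_image"))
  chans <- tile$channels
  is_int16 <- vapply(chans, function(m) {
    all(m == round(m)) && max(m) <= 65535
  }, logical(1))
  scales <- ifelse(is_int16, 65535, vapply(chans, function(m) max(max(m), 1), 1))
  pages <- map2(chans, scales, function(m, s) m / s)
  bits <- if (all(is_int16)) 16L else 32L
  if (bits == 16L) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  meta <- list(
    roles = names(chans),
    scales = unname(as.numeric(scales)),
    bits = bits,
    pixel_size_um = tile$pixel_size_um,
    grid_pos = as.integer(tile$grid_pos)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tile
#' @param roles Optional character vector naming the role of each TIFF page,
#'   overriding the sidecar.
#' @param pixel_size_um,grid_pos Overrides when no sidecar is present.
#' @export
read_tile <- function(path, roles = NULL, pixel_size_um = NULL,
                      grid_pos = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  roles <- roles %||% meta$roles
  if (is.null(roles)) abort("channel roles not given and no sidecar found")
  if (length(roles) > length(pages)) {
    missing_role <- setdiff(roles, roles[seq_along(pages)])
    abort(paste0("missing channel: ", missing_role[1]))
  }
  if (!"membrane" %in% roles) abort("missing channel: membrane")
  scales <- meta$scales %||% rep(1, length(pages))
  bits <- meta$bits %||% 32L
  chans <- map2(pages[seq_along(roles)], scales[seq_along(roles)],
                function(p, s) {
                  if (!is.matrix(p)) p <- p[, , 1]
                  v <- p * s
                  if (bits == 16L) v <- round(v)
                  v
                })
  names(chans) <- roles
  tile_image(chans,
             pixel_size_um = pixel_size_um %||% meta$pixel_size_um %||% 1,
             grid_pos = grid_pos %||% meta$grid_pos %||% c(0L, 0L))
}

#' Gaussian vignetting model
#'
#' Optical vignetting darkens tile corners; it is modelled as a
#' multiplicative gain field `gain(x, y) = baseline + amplitude *
#' exp(-d^2 / (2 sigma^2))`, `d` the distance to the field centre.
#' Correction divides by the gain and rescales so the image mean is
#' preserved.
#'
#' @param center `(x, y)` of the gain peak in pixels.
#' @param sigma_px Gaussian width in pixels (> 0).
#' @param amplitude,baseline Gain parameters (amplitude >= 0).
#' @return A `vignette_model` object.
#' @export
vignette_model <- function(center, sigma_px, amplitude, baseline) {
  if (sigma_px <= 0) abort("sigma_px must be > 0")
  if (amplitude < 0) abort("amplitude must be >= 0")
  structure(list(center = as.numeric(center), sigma_px = sigma_px,
                 amplitude = amplitude, baseline = baseline),
            class = "vignette_model")
}

vignette_gain <- function(model, side_px) {
  x <- matrix(rep(0:(side_px - 1), each = side_px), side_px, side_px)
  y <- matrix(rep(0:(side_px - 1), side_px), side_px, side_px)
  d2 <- (x - model$center[1])^2 + (y - model$center[2])^2
  model$baseline + model$amplitude * exp(-d2 / (2 * model$sigma_px^2))
}

#' Fit the vignetting gain of a channel
#'
#' Least-squares fit of a centred Gaussian gain to a coarse grid of local
#' medians of the channel (medians are robust to cells and dots riding on
#' the illumination field). Degenerate fits (vanishing width or negative
#' amplitude) fall back to the identity model with a warning.
#'
#' @param channel A 2-D intensity matrix with positive mean.
#' @param grid_n Coarse grid size for local medians.
#' @return A [vignette_model()].
#' @export
fit_vignette <- function(channel, grid_n = 16L) {
  s <- nrow(channel)
  if (mean(channel) <= 0) abort("channel must have positive mean")
  br <- floor(seq(0, s, length.out = grid_n + 1))
  mid <- (head(br, -1) + tail(br, -1)) / 2
  med <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      med[i, j] <- median(channel[(br[i] + 1):br[i + 1],
                                  (br[j] + 1):br[j + 1]])
    }
  }
  cx <- (s - 1) / 2
  d2 <- outer(mid - cx, mid - cx, function(a, b) a^2 + b^2)
  df <- data.frame(v = as.vector(med), d2 = as.vector(d2))
  identity_model <- vignette_model(c(cx, cx), sigma_px = s, amplitude = 0,
                                   baseline = 1)
  if (diff(range(df$v)) <= 1e-12 * max(abs(df$v), 1)) {
    return(identity_model)  # flat image: amplitude ~ 0
  }
  fit <- tryCatch(
    suppressWarnings(
      nls(v ~ b + a * exp(-d2 / (2 * sg^2)), data = df,
          start = list(b = min(df$v), a = diff(range(df$v)),
                       sg = s / 3),
          control = list(warnOnly = TRUE))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("vignette fit failed; using identity model")
    return(identity_model)
  }
  p <- coef(fit)
  d2max <- 2 * cx^2  # corner distance^2 from the centre
  gain_min <- p[["b"]] + p[["a"]] * exp(-d2max / (2 * p[["sg"]]^2))
  gain_max <- p[["b"]] + p[["a"]]
  if (!is.finite(p[["sg"]]) || abs(p[["sg"]]) < 1 || p[["a"]] < 0 ||
      gain_max <= 0 || gain_min <= 0.02 * gain_max) {
    warn("degenerate vignette fit; using identity model")
    return(identity_model)
  }
  vignette_model(c(cx, cx), sigma_px = abs(p[["sg"]]),
                 amplitude = p[["a"]], baseline = p[["b"]])
}

#' @rdname fit_vignette
#' @param tile A [tile_image()].
#' @param model A [vignette_model()], or a named list of models per channel
#'   role; by default each channel is fit independently.
#' @details Correction is not idempotent: applying the same non-trivial
#'   model twice divides by the gain twice.
#' @return `correct_vignette()`: the corrected `tile_image`.
#' @export
correct_vignette <- function(tile, model = NULL) {
  stopifnot(inherits(tile, "tile_image"))
  out <- tile
  for (nm in names(tile$channels)) {
    ch <- tile$channels[[nm]]
    m <- if (is.null(model)) fit_vignette(ch)
         else if (inherits(model, "vignette_model")) model
         else model[[nm]]
    gain <- vignette_gain(m, nrow(ch))
    corr <- ch / gain
    mu <- mean(corr)
    if (mu > 0) corr <- corr * (mean(ch) / mu)  # preserve image mean
    out$channels[[nm]] <- corr
  }
  out
}
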