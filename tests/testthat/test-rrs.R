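# Reaction seeding, ridge tracing, net construction and loop extraction.

test_that("seed sampling respects eligibility and warns on shortfall", {
  zero <- matrix(0, 64, 64)
  expect_warning(s0 <- sample_seeds(zero, params = rrs_params(n_seeds = 10)),
                 "constant")
  expect_equal(nrow(s0), 0)

  img <- matrix(1, 64, 64)
  bright <- cbind(sample(5:60, 10), sample(5:60, 10))
  img[bright] <- 100
  p <- rrs_params(n_seeds = 5, seed_intensity_percentile = 99.9)
  s <- sample_seeds(img, params = p, rng_seed = 4)
  expect_equal(nrow(s), 5)
  # all seeds among the 10 bright pixels (row = y+1, col = x+1)
  expect_true(all(img[cbind(s$y + 1, s$x + 1)] == 100))

  p2 <- rrs_params(n_seeds = 50, seed_intensity_percentile = 99.9)
  expect_warning(s2 <- sample_seeds(img, params = p2, rng_seed = 4),
                 "eligible")
  expect_equal(nrow(s2), 10)
})

test_that("seeds concentrate on a ring phantom", {
  img <- ring_phantom()
  # choose the percentile so the eligible set is the ridge band itself:
  # pixels within 2 px of the circle number ~ 2*pi*20*4
  n_band <- sum(abs(sqrt(outer((0:100 - 50)^2, (0:100 - 50)^2, `+`)) - 20) <= 2)
  pct <- 100 * (1 - 0.8 * n_band / 101^2)
  p <- rrs_params(n_seeds = 200, seed_intensity_percentile = pct)
  s <- sample_seeds(img, params = p, rng_seed = 1)
  d <- abs(sqrt((s$x - 50)^2 + (s$y - 50)^2) - 20)
  expect_gte(mean(d <= 2), 0.95)
})

test_that("a circular ridge traces to a closed loop of the right perimeter", {
  img <- ring_phantom()
  tp <- trace_from_seed(img, c(70, 50), rrs_params())
  expect_true(tp$closed)
  expect_lt(abs(tp$length_px - 2 * pi * 20) / (2 * pi * 20), 0.1)
  # consecutive points within step * 1.5
  steps <- sqrt(diff(tp$points[, 1])^2 + diff(tp$points[, 2])^2)
  expect_true(all(steps <= rrs_params()$step_px * 1.5 + 1e-9))
})

test_that("a straight ridge to the mask edge stays an open path", {
  img <- matrix(8, 101, 101)
  img[, 51] <- 128  # vertical ridge at x = 50 spanning the full image
  tp <- trace_from_seed(img, c(50, 50), rrs_params())
  expect_false(tp$closed)
  expect_gt(nrow(tp$points), 20)
})

test_that("uniform or empty images terminate walks immediately", {
  flat <- matrix(50, 64, 64)
  tp <- trace_from_seed(flat, c(32, 32), rrs_params())
  expect_false(tp$closed)
  expect_lte(nrow(tp$points), 5)
  zero <- matrix(0, 64, 64)
  tp0 <- trace_from_seed(zero, c(32, 32), rrs_params())
  expect_equal(length(tp0$step_loglik), 0)
})

test_that("net building rasterises closed traces into a thin ring", {
  img <- ring_phantom()
  tp <- trace_from_seed(img, c(70, 50), rrs_params())
  net <- build_net(list(tp), dim(img))
  expect_gt(sum(net$raster), 0)
  # net pixels hug the true circle
  idx <- which(net$raster, arr.ind = TRUE)
  d <- abs(sqrt((idx[, 2] - 1 - 50)^2 + (idx[, 1] - 1 - 50)^2) - 20)
  expect_lt(max(d), 3)
  # idempotent union: two identical traces, same net
  net2 <- build_net(list(tp, tp), dim(img))
  expect_identical(net$raster, net2$raster)
  # empty trace list -> empty net
  net0 <- build_net(list(), dim(img))
  expect_equal(sum(net0$raster), 0)
})

test_that("a perfect ring yields exactly one loop with the disc area", {
  img <- ring_phantom()
  net <- build_net(list(trace_from_seed(img, c(70, 50), rrs_params())),
                   dim(img))
  loops <- extract_loops(net, area_bounds_px2 = c(300, 3000),
                         coverage_min = 0.9)
  expect_equal(nrow(loops), 1)
  expect_lt(abs(loops$area_px2[1] - pi * 400) / (pi * 400), 0.05)
  # centroid near the centre and inside the polygon
  expect_lt(abs(loops$centroid_x[1] - 50), 2)
  expect_true(rrsfish:::points_in_polygon(loops$centroid_x[1],
                                          loops$centroid_y[1],
                                          loops$polygon[[1]]))
  # counter-clockwise orientation (positive shoelace)
  expect_gt(rrsfish:::polygon_signed_area(loops$polygon[[1]]), 0)
})

test_that("a broken ring is rejected by boundary coverage", {
  # ring with a 30% angular gap is not enclosed at all -> no bounded region;
  # a bounded region walled off partly by non-net structure fails coverage
  raster <- matrix(FALSE, 101, 101)
  th <- seq(0, 2 * pi, length.out = 720)
  keep <- th < 0.7 * 2 * pi
  raster[cbind(round(50 + 20 * sin(th[keep])) + 1,
               round(50 + 20 * cos(th[keep])) + 1)] <- TRUE
  loops <- extract_loops(structure(list(raster = raster), class = "membrane_net"),
                         c(300, 3000), coverage_min = 0.9)
  expect_equal(nrow(loops), 0)
})

test_that("segmentation is deterministic under a fixed seed", {
  gt <- small_scene(12, frame = c(130, 130), seed = 8)
  lay <- mosaic_layout(1, 1, 260, 0, 0.5)
  tiles <- render_tiles(gt, optics_config(tile_side_px = 260, rng_seed = 2),
                        lay)
  mem <- tiles[[1]]$channels$membrane
  p <- rrs_params(n_seeds = 1500)
  a <- rrs_segment(mem, params = p, area_bounds_px2 = c(100, 1000),
                   rng_seed = 77)
  b <- rrs_segment(mem, params = p, area_bounds_px2 = c(100, 1000),
                   rng_seed = 77)
  expect_identical(a$loops, b$loops)
  expect_identical(a$seeds, b$seeds)
})

test_that("returned loops never overlap by more than 10% of the smaller", {
  gt <- small_scene(20, frame = c(150, 150), seed = 13)
  lay <- mosaic_layout(1, 1, 300, 0, 0.5)
  tiles <- render_tiles(gt, noiseless_optics(300), lay)
  res <- analyze_tile(tiles[[1]], lay, rng_seed = 3,
                      cell_diameter_um = c(8, 14))
  loops <- res$loops
  expect_gt(nrow(loops), 5)
  shape <- dim(tiles[[1]]$channels$membrane)
  # loops_label_image aborts if the pairwise overlap exceeds 10%
  expect_no_error(rrsfish:::loops_label_image(loops, shape))
})

test_that("more seeds never recover fewer cells on a fixed phantom", {
  hb <- honeycomb_layout(5, 5, hex_radius_um = 7, rng_seed = 2,
                         frame_um = c(110, 110))
  lay <- mosaic_layout(1, 1, 220, 0, 0.5)
  tiles <- render_tiles(hb, noiseless_optics(220), lay,
                        channels = "membrane")
  rec <- vapply(c(400L, 1500L, 4000L), function(ns) {
    tab <- analyze_mosaic(tiles, lay, rng_seed = 5,
                          rrs = rrs_params(n_seeds = ns),
                          cell_diameter_um = c(9, 20), vignette = FALSE)
    match_cells(tab, hb)$n_matched
  }, 1L)
  expect_true(all(diff(rec) >= 0))
  expect_gte(rec[3], 24)
})
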