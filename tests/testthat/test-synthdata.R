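# Ground-truth generator and renderer.

pheno2 <- list(phenotype_spec("A", c(rna_1 = 8)),
               phenotype_spec("B", c(rna_1 = 0.2)))

test_that("empty scene and exact phenotype apportionment", {
  gt0 <- generate_layout(0, c(100, 100), phenotype_mix = c(A = 0.25, B = 0.75),
                         phenotypes = pheno2, rng_seed = 1)
  expect_equal(nrow(gt0$cells), 0)

  gt <- generate_layout(100, c(450, 450), c(8, 14),
                        phenotype_mix = c(A = 0.25, B = 0.75),
                        phenotypes = pheno2, rng_seed = 1)
  expect_equal(as.vector(table(gt$cells$phenotype)[c("A", "B")]),
               c(25L, 75L))
})

test_that("largest-remainder apportionment is exact for awkward mixes", {
  for (n in c(7, 100, 33)) {
    for (mix in list(c(A = 1 / 3, B = 2 / 3), c(A = 0.5, B = 0.5),
                     c(A = 0.21, B = 0.79))) {
      cnt <- rrsfish:::largest_remainder(n, mix)
      expect_identical(sum(cnt), as.integer(n))
      expect_true(all(abs(cnt - n * mix) < 1))
    }
  }
  expect_error(generate_layout(10, c(100, 100),
                               phenotype_mix = c(A = 0.6, B = 0.6),
                               phenotypes = pheno2),
               "sum to 1")
})

test_that("spot counts follow the phenotype Poisson rate", {
  gt <- generate_layout(200, c(650, 650), c(8, 14),
                        phenotype_mix = c(A = 1),
                        phenotypes = list(phenotype_spec("A", c(rna_1 = 8))),
                        rng_seed = 42)
  m <- mean(true_counts(gt)$rna_1)
  expect_gt(m, 7.0)  # 99% interval of a Poisson(8) mean at n = 200
  expect_lt(m, 9.0)
})

test_that("ground-truth geometry invariants hold", {
  gt <- small_scene(40, frame = c(200, 200), seed = 3)
  # polygons simple/convex and pairwise non-overlapping; spots inside cells
  for (i in seq_len(nrow(gt$cells))) {
    p <- gt$cells$polygon[[i]]
    expect_gt(abs(rrsfish:::polygon_signed_area(p)), 0)
    sp <- gt$cells$spots[[i]]$rna_1
    if (nrow(sp)) {
      expect_true(all(rrsfish:::points_in_polygon(sp[, 1], sp[, 2], p)))
    }
  }
  centres <- cbind(gt$cells$x_um, gt$cells$y_um)
  d <- as.matrix(dist(centres)); diag(d) <- Inf
  # no two cells closer than the sum of their maximal vertex radii
  lim <- outer(gt$cells$radius_um, gt$cells$radius_um,
               function(a, b) 1.2 * a + 1.2 * b)
  expect_true(all(d > lim - 1e-9))
})

test_that("dilution series realises round(n * ratio * purity) positives", {
  ser <- make_dilution_series(0.9, c(0.75, 0), n_cells = 40, rng_seed = 1,
                              frame_um = c(320, 320))
  expect_equal(attr(ser[[1]], "n_positive"), 27L)  # 40 * .75 * .9
  expect_equal(sum(ser[[1]]$cells$phenotype == "car_pos"), 27L)
  expect_equal(attr(ser[[2]], "n_positive"), 0L)
  expect_equal(sum(ser[[2]]$cells$phenotype == "car_pos"), 0L)
  ser2 <- make_dilution_series(1.0, 0.5, n_cells = 10, rng_seed = 1,
                               frame_um = c(200, 200))
  expect_equal(attr(ser2[[1]], "n_positive"), 5L)
})

test_that("rendering is deterministic and respects the optics model", {
  gt <- small_scene(10, frame = c(120, 120), seed = 5)
  lay <- mosaic_layout(1, 1, 240, 0, 0.5)
  opt <- optics_config(tile_side_px = 240, rng_seed = 9)
  t1 <- render_tiles(gt, opt, lay)
  t2 <- render_tiles(gt, opt, lay)
  expect_identical(t1[[1]]$channels, t2[[1]]$channels)  # bit-identical

  # membrane maximum of an isolated cell lies on its boundary (+/- ridge w)
  opt0 <- noiseless_optics(240, seed = 9)
  tl <- render_tiles(gt, opt0, lay)[[1]]
  i <- 1
  poly_px <- gt$cells$polygon[[i]] / 0.5
  bb <- tl$channels$membrane
  sub_idx <- which(bb == max(bb[
    round(min(poly_px[, 2])):round(max(poly_px[, 2])) + 1,
    round(min(poly_px[, 1])):round(max(poly_px[, 1])) + 1]), arr.ind = TRUE)
  d <- rrsfish:::dist_to_segments(sub_idx[1, 2] - 1, sub_idx[1, 1] - 1,
                                  poly_px)
  expect_lt(min(d), opt0$membrane_ridge_width_px)
})

test_that("vignette gain follows the configured Gaussian exactly", {
  # uniform background scene, zero noise: corner/centre ratio = exp(-r^2/2s^2)
  gt <- generate_layout(0, c(130, 130), phenotype_mix = c(A = 1),
                        phenotypes = list(phenotype_spec("A")), rng_seed = 1)
  lay <- mosaic_layout(1, 1, 256, 0, 0.5)
  opt <- noiseless_optics(256)
  tl <- render_tiles(gt, opt, lay)[[1]]
  m <- tl$channels$membrane
  ctr <- (256 - 1) / 2
  sig <- opt$vignette_sigma_frac * 256
  r2 <- 2 * ctr^2
  expect_equal(m[1, 1] / m[128, 128],
               exp(-r2 / (2 * sig^2)) /
                 exp(-((127 - ctr)^2 * 2) / (2 * sig^2)),
               tolerance = 1e-6)
})

test_that("spot-count conservation: truth equals rendered spot centres", {
  gt <- small_scene(25, frame = c(150, 150), seed = 11)
  tc <- true_counts(gt)
  n_centres <- sum(vapply(gt$cells$spots, function(s) nrow(s$rna_1), 1L))
  expect_identical(sum(tc$rna_1), as.integer(n_centres))
})

test_that("generator determinism: same seed, same scene", {
  a <- small_scene(15, seed = 21)
  b <- small_scene(15, seed = 21)
  expect_identical(a$cells, b$cells)
  c <- small_scene(15, seed = 22)
  expect_false(identical(a$cells$x_um, c$cells$x_um))
})

test_that("placement failure reports the achieved density", {
  expect_error(
    generate_layout(500, c(100, 100), c(12, 14),
                    phenotype_mix = c(A = 1),
                    phenotypes = list(phenotype_spec("A")),
                    max_attempts = 50),
    "cells/mm")
})

test_that("ground truth serialises to JSON with micrometre polygons", {
  gt <- small_scene(5, frame = c(120, 120), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$frame_um, c(120, 120))
  expect_equal(length(back$cells$cell_id), 5)
})
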