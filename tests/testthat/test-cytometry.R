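# Cell-table assembly, CSV round trip, gating and the dilution fit.

# Minimal hand-built tile results: loops made from square outlines.
square_loops <- function(origins, w = 20, side = 101) {
  raster <- matrix(FALSE, side, side)
  for (o in origins) {
    for (t in 0:w) {
      raster[o[2] + 1, o[1] + t + 1] <- TRUE
      raster[o[2] + w + 1, o[1] + t + 1] <- TRUE
      raster[o[2] + t + 1, o[1] + 1] <- TRUE
      raster[o[2] + t + 1, o[1] + w + 1] <- TRUE
    }
  }
  extract_loops(structure(list(raster = raster), class = "membrane_net"),
                c(50, 2000), coverage_min = 0.9)
}

fake_result <- function(grid_pos, origins, side = 101) {
  loops <- square_loops(origins, side = side)
  list(loops = loops,
       dots = list(rna_1 = tibble::tibble(loop_id = loops$loop_id,
                                          n = loops$loop_id + 1L)),
       nuclei = tibble::tibble(loop_id = loops$loop_id, n = 1L),
       ihc = tibble::tibble(loop_id = loops$loop_id, ihc = 5),
       grid_pos = grid_pos)
}

test_that("records from multiple tiles get unique ids and global coords", {
  lay <- mosaic_layout(1, 2, 101, 0, 0.5)
  res <- list(fake_result(c(0, 0), list(c(10, 10), c(60, 60), c(10, 60))),
              fake_result(c(0, 1), list(c(10, 10), c(60, 60), c(60, 10))))
  tab <- build_cell_table(res, lay)
  expect_equal(nrow(tab), 6)
  expect_equal(anyDuplicated(tab$cell_id), 0)
  # second tile offset by side_px * pixel_size
  expect_true(all(tab$x_um[tab$tile_col == 1] >= 101 * 0.5 * 0.19))
  # deterministic ordering
  expect_true(!is.unsorted(tab$cell_id))
})

test_that("loops with centroids in the border strip are dropped", {
  lay <- mosaic_layout(1, 1, 101, 25, 0.5)
  # square at origin 10 has centroid ~20 -> inside border strip (25)
  res <- fake_result(c(0, 0), list(c(10, 10), c(40, 40)))
  tab <- build_cell_table(list(res), lay)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$x_um, 25 * 0.5)
})

test_that("CSV export is the numeric flow-style schema and round-trips", {
  lay <- mosaic_layout(1, 1, 101, 0, 0.5)
  res <- fake_result(c(0, 0), list(c(10, 10), c(60, 60)))
  tab <- build_cell_table(list(res), lay, rna_names = c(rna_1 = "CAR"))
  path <- withr::local_tempfile(fileext = ".csv")
  export_cells_csv(tab, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "cell_id,x_um,y_um,area_um2,nuclei,CAR,ihc")
  back <- import_cells_csv(path, lay)
  for (cl in c("cell_id", "x_um", "y_um", "area_um2", "nuclei", "CAR",
               "ihc")) {
    expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-9)
  }
  # empty table -> header-only file
  e <- tab[0, ]
  attr(e, "rna_roles") <- "CAR"
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_cells_csv(e, path2)
  expect_equal(length(readLines(path2)), 1)
})

test_that("gates AND their rules and summarise fractions", {
  tab <- toy_cell_table(200, seed = 3)
  g_all <- gate_cells(tab, gate_spec("GZMB>=0", "GZMB", 0))
  expect_equal(g_all$fraction, 1.0)
  g <- gate_cells(tab, gate_spec("CD19+GZMB+", c("CD19", "GZMB"), c(3, 3)))
  expect_equal(g$n_pos, sum(tab$CD19 >= 3 & tab$GZMB >= 3))
  # (CAR=5, GZMB=0) is negative under CAR>=3 AND GZMB>=3
  one <- tab[1, ]; one$CD19 <- 5; one$GZMB <- 0
  expect_equal(gate_cells(one, gate_spec("x", c("CD19", "GZMB"),
                                         c(3, 3)))$n_pos, 0)
  expect_error(gate_cells(tab, gate_spec("x", "missing_role", 1)),
               "not in table")
  # empty table flagged undefined
  g0 <- gate_cells(tab[0, ], gate_spec("x", "CD19", 1))
  expect_true(g0$undefined)
  expect_equal(g0$n_pos, 0L)
})

test_that("a partition of gate space has fractions summing to 1", {
  tab <- toy_cell_table(300, seed = 9)
  f <- c(
    gate_cells(tab, gate_spec("a", c("CD19", "GZMB"), c(3, 2)))$fraction,
    gate_cells(tab, gate_spec("b", c("CD19", "GZMB"), c(3, 2),
                              c(">=", "<")))$fraction,
    gate_cells(tab, gate_spec("c", "CD19", 3, "<"))$fraction)
  expect_equal(sum(f), 1)
})

test_that("export -> import -> gate equals gating in memory", {
  tab <- toy_cell_table(150, seed = 5)
  spec <- gate_spec("CD19+", "CD19", 3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_cells_csv(tab, path)
  back <- import_cells_csv(path, attr(tab, "layout"))
  expect_identical(gate_cells(back, spec)$n_pos, gate_cells(tab, spec)$n_pos)
})

test_that("expected positive fractions match the mixing design", {
  expect_equal(expected_positive_fraction(0.90, 0.75), 67.5)
  expect_equal(expected_positive_fraction(0.90, 0.25), 22.5)
  expect_equal(expected_positive_fraction(0.33, 0), 0)
  expect_error(expected_positive_fraction(1.2, 0.5), "0, 1")
})

test_that("dilution fit recovers slope, intercept and R^2", {
  f1 <- dilution_fit(c(0, .225, .45, .675, .9), c(0, .225, .45, .675, .9))
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  expect_equal(f1$r_squared, 1)
  f2 <- dilution_fit(2 * c(.1, .4, .9), c(.1, .4, .9))
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)
  f3 <- dilution_fit(c(0.05, 0.24, 0.44, 0.65, 0.88),
                     c(0, .225, .45, .675, .90))
  expect_gte(f3$r_squared, 0.99)
  expect_error(dilution_fit(c(1, 2, 3), c(1, 1, 1)), "zero variance")
  expect_error(dilution_fit(1:2, 1:2), "length")
  # broom-style accessors
  expect_equal(glance(f3)$r_squared, f3$r_squared)
  expect_equal(tidy(f3)$estimate, c(f3$intercept, f3$slope))
})

test_that("IHC auto-gate separates two clear intensity classes", {
  tab <- toy_cell_table(200, seed = 10)
  withr::with_seed(99, tab$ihc <- c(rnorm(150, 5, 1), rnorm(50, 60, 5)))
  g <- gate_cells(tab, ihc_gate(tab))
  expect_equal(g$n_pos, 50)
})
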