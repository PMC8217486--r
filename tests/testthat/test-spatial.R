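# Circle-expansion tissue partition, densities, significance tests.

test_that("tissue area follows the occupied-tile arithmetic", {
  lay <- mosaic_layout(3, 3, 2048, 48, 0.5)
  tab <- toy_cell_table(10, seed = 1, frame = 900, layout = lay)
  expect_equal(tissue_area(tab, lay), (1952 * 0.5 / 1000)^2)  # 0.952576
  # cells spread over 3 tiles -> 3x the single-tile area
  tab3 <- tab
  tab3$tile_row <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L, 0L)
  tab3$tile_col <- 0L
  expect_equal(tissue_area(tab3, lay), 3 * (1952 * 0.5 / 1000)^2)
  expect_warning(a0 <- tissue_area(tab[0, ], lay), "empty")
  expect_equal(a0, 0)
})

test_that("two nearby cells with factor-16 expansion form one group", {
  lay <- mosaic_layout(1, 1, 2048, 48, 0.5)
  t2 <- tibble::tibble(cell_id = 1:2, x_um = c(400, 500), y_um = 500,
                       area_um2 = pi * 25, tile_row = 0L, tile_col = 0L,
                       nuclei = 1L, CD19 = 5L, ihc = 0)
  attr(t2, "layout") <- lay
  class(t2) <- c("cell_table", class(t2))
  # r = 5, R = 80; 80 + 80 > 100 -> one connective group of two
  p <- cd19_partition(t2, gate_spec("CD19+", "CD19", 3),
                      partition_params(16), lay)
  expect_equal(p$n_groups, 1L)
  expect_equal(sort(p$member_ids), 1:2)
  # both cells assigned high
  expect_true(all(p$assignment$region == "high"))
})

test_that("the largest group wins and far cells stay low", {
  lay <- mosaic_layout(1, 1, 2048, 48, 0.5)
  tab <- tibble::tibble(
    cell_id = 1:5,
    x_um = c(200, 220, 240, 900, 560), y_um = c(200, 215, 200, 900, 555),
    area_um2 = pi * 25, tile_row = 0L, tile_col = 0L, nuclei = 1L,
    CD19 = c(5L, 5L, 5L, 5L, 0L), ihc = 0)
  attr(tab, "layout") <- lay
  class(tab) <- c("cell_table", class(tab))
  p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3),
                      partition_params(16), lay)
  expect_equal(sort(p$member_ids), 1:3)
  asg <- p$assignment
  expect_equal(asg$region[asg$cell_id == 4], "low")
})

test_that("zero marker-positive cells give an empty, flagged high region", {
  tab <- toy_cell_table(50, seed = 2)
  tab$CD19 <- 0L
  expect_warning(
    p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3)),
    "no marker-positive")
  expect_true(p$empty_high)
  expect_equal(p$area_high_mm2, 0)
  expect_true(all(p$assignment$region == "low"))
  expect_equal(p$area_low_mm2, p$area_tissue_mm2)
})

test_that("connective groups equal the brute-force pairwise oracle", {
  lay <- mosaic_layout(1, 1, 2048, 48, 0.5)
  for (k in 1:100) {
    withr::with_seed(1000 + k, {
      n <- sample(2:60, 1)
      x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
      r <- runif(n, 3, 8)
    })
    R <- 16 * r
    tab <- tibble::tibble(cell_id = seq_len(n), x_um = x, y_um = y,
                          area_um2 = pi * r^2, tile_row = 0L, tile_col = 0L,
                          nuclei = 1L, CD19 = 5L, ihc = 0)
    attr(tab, "layout") <- lay
    class(tab) <- c("cell_table", class(tab))
    p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3),
                        partition_params(16), lay)
    oracle <- brute_force_groups(x, y, R)
    # the winning group must be a largest oracle component
    oracle_sizes <- tabulate(oracle)
    expect_equal(length(p$member_ids), max(oracle_sizes))
    # and must be exactly one oracle component
    mem_comp <- unique(oracle[match(p$member_ids, tab$cell_id)])
    expect_equal(length(mem_comp), 1)
  }
})

test_that("high + low areas add to the tissue area within 0.5%", {
  for (k in 1:5) {
    tab <- toy_cell_table(200, seed = 40 + k)
    p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3))
    expect_lt(abs(p$area_high_mm2 + p$area_low_mm2 - p$area_tissue_mm2) /
                p$area_tissue_mm2, 0.005)
    # every cell assigned exactly once
    expect_identical(sort(p$assignment$cell_id), tab$cell_id)
  }
})

test_that("disc-union area agrees with 1-um rasterisation", {
  withr::with_seed(7, {
    x <- runif(30, 100, 400); y <- runif(30, 100, 400); r <- runif(30, 20, 60)
  })
  polys <- rrsfish:::discs_union(x, y, r)
  a_poly <- rrsfish:::poly_list_area(polys)
  gx <- seq(0, 520, by = 1); gy <- seq(0, 520, by = 1)
  g <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(g))
  for (i in seq_along(x)) {
    inside <- inside | ((g$x - x[i])^2 + (g$y - y[i])^2 <= r[i]^2)
  }
  expect_lt(abs(a_poly - sum(inside)) / sum(inside), 0.01)
})

test_that("larger expansion factors never shrink the winning group", {
  tab <- toy_cell_table(150, seed = 77)
  sizes <- vapply(c(4, 8, 16, 32), function(f) {
    p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3),
                        partition_params(f))
    length(p$member_ids)
  }, 1)
  expect_true(all(diff(sizes) >= 0))
})

test_that("a planted marker cluster is recovered as the high region", {
  gt <- generate_layout(
    300, c(1000, 1000), c(8, 14),
    phenotype_mix = c(tumour = 0.2, t_eff = 0.2, t_rest = 0.6),
    phenotypes = list(
      phenotype_spec("tumour", c(rna_1 = 0), ihc_level = 60),
      phenotype_spec("t_eff", c(rna_1 = 8)),
      phenotype_spec("t_rest", c(rna_1 = 8))),
    cluster = cluster_spec(c(500, 500), 150, c("tumour", "t_eff"),
                           enrichment = 25),
    rng_seed = 55)
  lay <- mosaic_layout(1, 1, 2048, 24, 0.5)
  tab <- tibble::tibble(
    cell_id = gt$cells$cell_id, x_um = gt$cells$x_um, y_um = gt$cells$y_um,
    area_um2 = pi * gt$cells$radius_um^2, tile_row = 0L, tile_col = 0L,
    nuclei = 1L, CD19 = ifelse(gt$cells$phenotype == "tumour", 5L, 0L),
    GZMB = ifelse(gt$cells$phenotype == "t_eff", 6L, 0L), ihc = 0)
  attr(tab, "layout") <- lay
  class(tab) <- c("cell_table", class(tab))
  p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3),
                      partition_params(16), lay)
  planted <- tab$cell_id[tab$CD19 >= 3 &
                           sqrt((tab$x_um - 500)^2 + (tab$y_um - 500)^2) <= 150]
  expect_gte(mean(planted %in% p$member_ids), 0.95)
  # enriched effector phenotype is denser in the high region
  dens <- spatial_density(tab, p, list(gate_spec("GZMB+", "GZMB", 3)))
  dh <- dens$density_mm2[dens$region == "high"]
  dl <- dens$density_mm2[dens$region == "low"]
  expect_gt(dh, dl)
})

test_that("density bookkeeping is exact and conserves counts", {
  tab <- toy_cell_table(200, seed = 12)
  p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3))
  gates <- list(gate_spec("GZMB+", "GZMB", 2),
                gate_spec("GZMB-", "GZMB", 2, "<"))
  dens <- spatial_density(tab, p, gates,
                          ratio_pairs = list(c("GZMB+", "GZMB-")))
  # counts sum to the table totals per phenotype
  for (lbl in c("GZMB+", "GZMB-")) {
    expect_equal(sum(dens$count[dens$phenotype == lbl]),
                 gate_cells(tab, gates[[which(c("GZMB+", "GZMB-") == lbl)]])$n_pos)
  }
  # density = count / area exactly
  nz <- dens$area_mm2 > 0
  expect_equal(dens$density_mm2[nz], dens$count[nz] / dens$area_mm2[nz])
  ratios <- attr(dens, "ratios")
  expect_equal(nrow(ratios), 2)
})

test_that("paired t test matches the hand-derived oracle", {
  r <- paired_t(c(2, 2, 2, 0), c(1, 1, 1, 1))  # d = {1,1,1,-1}
  expect_equal(r$t, 1.0)
  expect_equal(r$df, 3)
  # antisymmetry
  r2 <- paired_t(c(1, 1, 1, 1), c(2, 2, 2, 0))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # constant shift -> degenerate
  expect_error(paired_t(c(1, 2, 3) + 5, c(1, 2, 3)), "degenerate")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("one-way ANOVA matches the hand ANOVA table", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$F, 3.0)  # SSB = 6 (df 2), SSW = 6 (df 6)
  expect_equal(c(r$df1, r$df2), c(2, 6))
  expect_false(r$degenerate)
  # equal means -> F ~ 0 scale
  set.seed(2)
  g <- replicate(3, rnorm(20), simplify = FALSE)
  expect_lt(one_way_anova(g)$F, 5)
  # zero within-variance, distinct means -> flagged infinite F
  rd <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_true(rd$degenerate)
  expect_equal(rd$F, Inf)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(one_way_anova(list(1, 2)), "groups")
})

test_that("partition exports CSV and GeoJSON geometry", {
  tab <- toy_cell_table(80, seed = 3)
  p <- cd19_partition(tab, gate_spec("CD19+", "CD19", 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  gj <- withr::local_tempfile(fileext = ".geojson")
  export_partition(p, csv, gj)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 80)
  back <- jsonlite::read_json(gj)
  expect_equal(back$geometry$type, "MultiPolygon")
})
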