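test_that("pooled density is count over total stamp area", {
  cells <- cells_at(runif(100, 0, 670), runif(100, 0, 502), "CD8")
  d <- compute_densities(cells)
  border <- d[d$region == "border" & d$marker == "CD8", ]
  expect_equal(border$density_per_mm2, 100 / 0.33634, tolerance = 1e-12)
  expect_equal(stamp_geometry()$area_mm2, 0.33634)

  # invariant under rigid translation, scales inversely with stamp count
  shifted <- dplyr::mutate(cells, x_um = x_um + 50, y_um = y_um - 10)
  expect_equal(compute_densities(shifted)$density_per_mm2,
               d$density_per_mm2)
  stamps <- tibble::tibble(sample_id = "s1",
                           region = c("border", "center"),
                           n_stamps = c(4L, 4L))
  d4 <- compute_densities(cells, stamps = stamps)
  expect_equal(d4$density_per_mm2[d4$region == "border" & d4$marker == "CD8"],
               100 / (4 * 0.33634))
})

test_that("declared empty stamps give zero densities and stamp QC flags work", {
  cells <- cells_at(numeric(0), numeric(0), character(0))
  stamps <- tibble::tibble(sample_id = "s1",
                           region = c("border", "center"),
                           n_stamps = c(8L, 8L))
  d <- compute_densities(cells, stamps = stamps, markers = "CD8")
  expect_equal(d$density_per_mm2, c(0, 0))
  expect_equal(d$qc, c("ok", "ok"))

  # fewer than 3 stamps at a region flags the sample; no phenotype assigned
  few <- dplyr::bind_rows(
    cells_at(runif(200, 0, 670), runif(200, 0, 502), "CD8", stamp_id = "B01"),
    cells_at(runif(200, 0, 670), runif(200, 0, 502), "CD8", stamp_id = "B02"),
    cells_at(runif(30, 0, 670), runif(30, 0, 502), "CD8", stamp_id = "C01",
             region = "center"),
    cells_at(runif(30, 0, 670), runif(30, 0, 502), "CD8", stamp_id = "C02",
             region = "center"),
    cells_at(runif(30, 0, 670), runif(30, 0, 502), "CD8", stamp_id = "C03",
             region = "center"))
  out <- cd8_phenotypes(few)
  expect_equal(out$phenotype, "unassigned")
  expect_equal(out$reason, "insufficient_stamps")

  expect_error(compute_densities(
    dplyr::mutate(cells_at(1, 1, "CD8"), region = "edge")), "region")
})

test_that("digital threshold rule matches the published criteria", {
  expect_equal(
    assign_phenotype_digital(c(250, 250, 100, 180, 250, 100),
                             c(20, 100, 50, 5, 0, 200)),
    c("excluded", "inflamed", "ignored", "unassigned", "excluded",
      "unassigned"))
  det <- assign_phenotype_digital(c(180, 250, NA), c(5, 25, 10), detail = TRUE)
  expect_equal(det$reason, c("threshold_gap", "ratio_at_cutoff",
                             "missing_density"))
  expect_equal(det$phenotype, c("unassigned", "unassigned", "unassigned"))
  # zero center: ratio is +Inf
  expect_equal(assign_phenotype_digital(250, 0, detail = TRUE)$ratio, Inf)
  expect_error(assign_phenotype_digital(-1, 5), ">= 0")
})

test_that("the three digital predicates are mutually exclusive on a grid", {
  g <- expand.grid(border = seq(0, 1000, by = 5), center = seq(0, 1000, by = 5))
  th <- phenotype_thresholds()
  ratio <- ifelse(g$center == 0, ifelse(g$border > 0, Inf, NaN),
                  g$border / g$center)
  infl <- g$border > th$high_border & ratio < th$ratio_cut
  excl <- g$border > th$high_border & ratio > th$ratio_cut
  ign <- g$border < th$low_both & g$center < th$low_both
  expect_true(all(infl + excl + ign <= 1))
  lab <- assign_phenotype_digital(g$border, g$center, th)
  expect_equal(lab == "inflamed", unname(infl))
  expect_equal(lab == "excluded", unname(excl))
  expect_equal(lab == "ignored", unname(ign))
})

test_that("manual scoring mirrors the staining criteria on raw counts", {
  expect_equal(assign_phenotype_manual(c(500, 5, 300), c(20, 2, 250)),
               c("excluded", "ignored", "inflamed"))
  expect_equal(assign_phenotype_manual(9, 9), "ignored")
  expect_equal(assign_phenotype_manual(100, 0), "excluded")
})

test_that("digital assignment recovers the generating archetype", {
  hits <- 0L
  n_seeds <- 25L
  for (p in phenotype_levels()) {
    for (s in seq_len(n_seeds)) {
      cells <- sim_cell_pattern(p, seed = 1000L + s)
      hits <- hits + (cd8_phenotypes(cells)$phenotype == p)
    }
  }
  expect_gte(hits / (3 * n_seeds), 0.95)

  # excluded archetype with empty center: infinite ratio, still excluded
  intens <- tibble::tibble(marker = "CD8", border = 400, center = 0)
  cells <- sim_cell_pattern("excluded", intensities = intens, seed = 9)
  expect_equal(cd8_phenotypes(cells)$phenotype, "excluded")
})

test_that("neighbor counts match a brute-force all-pairs oracle", {
  set.seed(31) # test-local randomness for the fixture
  n <- 400
  cells <- tibble::tibble(
    sample_id = "s1",
    stamp_id = sample(c("B01", "B02", "C01"), n, replace = TRUE),
    region = "border",
    compartment = "tumor",
    marker = sample(c("CD8", "CK", "CD68"), n, replace = TRUE),
    x_um = runif(n, 0, 200), y_um = runif(n, 0, 150))
  got <- count_neighbors(cells, "CD8", radius_um = 25)
  want <- brute_force_neighbors(cells, "CD8", 25)
  expect_equal(got[, c("ref_cell", "marker", "n_neighbors")], want)

  # aggregate symmetry: A-near-B pairs equal B-near-A pairs
  ab <- sum(count_neighbors(cells, "CD8")$n_neighbors[
    count_neighbors(cells, "CD8")$marker == "CK"])
  ba <- sum(count_neighbors(cells, "CK")$n_neighbors[
    count_neighbors(cells, "CK")$marker == "CD8"])
  expect_equal(ab, ba)
})

test_that("radius test is a closed ball and stamps are disjoint", {
  two <- dplyr::bind_rows(cells_at(0, 0, "CD8"), cells_at(10, 0, "CK"))
  nb <- count_neighbors(two, "CD8", radius_um = 10)
  expect_equal(nb$n_neighbors[nb$marker == "CK"], 1L)

  across <- dplyr::bind_rows(cells_at(0, 0, "CD8", stamp_id = "B01"),
                             cells_at(1, 0, "CK", stamp_id = "B02"))
  nb2 <- count_neighbors(across, "CD8", radius_um = 10)
  expect_equal(nb2$n_neighbors[nb2$marker == "CK"], 0L)

  expect_warning(count_neighbors(two, "CD4"), "absent")
})

test_that("nearest-neighbor distances match hand values and brute force", {
  cells <- dplyr::bind_rows(cells_at(0, 0, "CD8"),
                            cells_at(3, 4, "CK"),
                            cells_at(6, 8, "CK"))
  expect_equal(mean_nearest_distance(cells, "CD8", "CK"), 5)

  # self-marker: nearest other cell of the same marker
  trio <- dplyr::bind_rows(cells_at(0, 0, "CD8"), cells_at(0, 1, "CD8"),
                           cells_at(0, 5, "CD8"))
  expect_equal(mean_nearest_distance(trio, "CD8", "CD8"), (1 + 1 + 4) / 3)

  set.seed(17)
  n <- 300
  rnd <- tibble::tibble(
    sample_id = "s1",
    stamp_id = sample(c("B01", "B02"), n, replace = TRUE),
    region = "border", compartment = "stroma",
    marker = sample(c("CD8", "CK"), n, replace = TRUE),
    x_um = runif(n, 0, 300), y_um = runif(n, 0, 300))
  expect_equal(sort(nearest_distances(rnd, "CD8", "CK")$nn_dist_um),
               sort(brute_force_nearest(rnd, "CD8", "CK")))

  expect_warning(md <- mean_nearest_distance(cells, "CD8", "CD56"), "pairs")
  expect_true(is.na(md))
})
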