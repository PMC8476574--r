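test_that("spearman_rho matches hand values and the Pearson-on-ranks oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- round(rnorm(n), 1) # rounding induces ties
    y <- round(rnorm(n), 1)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    oracle <- stats::cor(rank(x, ties.method = "average"),
                         rank(y, ties.method = "average"))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }

  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_warning(r <- spearman_rho(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(r))
})

test_that("Welch statistics agree with stats::t.test per gene", {
  set.seed(5)
  m1 <- matrix(rnorm(50, mean = 1), nrow = 5)
  m2 <- matrix(rnorm(40), nrow = 5)
  w <- spatialpheno:::welch_rows(m1, m2)
  for (g in 1:5) {
    tt <- t.test(m1[g, ], m2[g, ])
    expect_equal(w$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df[g], unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("gene selection recovers planted markers with correct signatures", {
  recalls <- fp_rates <- numeric(0)
  for (s in 1:5) {
    cohort <- tiny_cohort(seed = 100 + s, n = 30, markers = 20, noise = 500)
    genes <- select_classifier_genes(cohort)
    planted <- grep("^NOISE_", cohort$expression$gene_id, invert = TRUE,
                    value = TRUE)
    recalls <- c(recalls, mean(planted %in% genes$gene_id))
    fp_rates <- c(fp_rates, mean(grepl("^NOISE_", genes$gene_id)))
    # signature phenotype must match the planted block
    hit <- genes[genes$gene_id %in% planted, ]
    block <- c(EXC = "excluded", IGN = "ignored", INF = "inflamed")
    expect_equal(hit$signature_phenotype,
                 unname(block[substr(hit$gene_id, 1, 3)]))
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fp_rates), 0.05)
})

test_that("a gene high in two phenotypes is not selected (all-pairwise rule)", {
  # 6 samples per phenotype; gene high in excluded AND ignored, flat otherwise
  set.seed(42)
  n <- 6
  lab <- rep(phenotype_levels(), each = n)
  ids <- paste0("s", seq_along(lab))
  ns <- length(lab)
  shared <- ifelse(lab %in% c("excluded", "ignored"), 9, 5) + rnorm(ns, 0, 0.1)
  marker <- vapply(phenotype_levels(),
                   function(p) ifelse(lab == p, 9, 5) + rnorm(ns, 0, 0.1),
                   numeric(ns))
  expr <- tibble::tibble(gene_id = c("SHARED", "MK_EXC", "MK_IGN", "MK_INF",
                                     paste0("N", 1:20)))
  vals <- rbind(shared, t(marker),
                matrix(rnorm(20 * ns, 5, 0.1), nrow = 20))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(
    matrix(vals, ncol = ns, dimnames = list(NULL, ids))))
  ann <- tibble::tibble(sample_id = ids, stained_phenotype = lab)
  genes <- select_classifier_genes(expr, ann)
  expect_false("SHARED" %in% genes$gene_id)
  expect_equal(genes$signature_phenotype[match(
    c("MK_EXC", "MK_IGN", "MK_INF"), genes$gene_id)], phenotype_levels())
})

test_that("selection fails loudly on null cohorts and bad inputs", {
  null_cohort <- tiny_cohort(seed = 3, n = 20, markers = 5, noise = 100,
                             effect = 0)
  expect_error(select_classifier_genes(null_cohort), "selection failed")

  cohort <- tiny_cohort(seed = 4, n = 5, markers = 3, noise = 10)
  ann <- cohort$annotations
  ann$stained_phenotype[ann$stained_phenotype == "ignored"] <- NA
  expect_error(select_classifier_genes(cohort$expression, ann), "label")
  one_sample <- dplyr::filter(
    cohort$annotations,
    stained_phenotype != "ignored" | sample_id == sample_id[1])
  expr_sub <- cohort$expression[, c("gene_id", one_sample$sample_id)]
  expect_error(select_classifier_genes(expr_sub, one_sample), ">= 2 samples")
})

test_that("centroid ranks follow the ascending average-rank convention", {
  lab <- rep(phenotype_levels(), each = 2)
  ids <- paste0("s", 1:6)
  vals <- rbind(c(9, 9, 5, 5, 1, 1),
                c(5, 5, 5, 5, 5, 5),
                c(1, 1, 5, 5, 9, 9))
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = c("g1", "g2", "g3")),
    tibble::as_tibble(matrix(vals, ncol = 6, dimnames = list(NULL, ids))))
  ann <- tibble::tibble(sample_id = ids, stained_phenotype = lab)
  model <- build_classifier(expr, ann, genes = c("g1", "g2", "g3"))
  tbl <- tidy(model)
  expect_equal(tbl$mean_excluded, c(9, 5, 1))
  expect_equal(tbl$rank_excluded, c(3, 2, 1)) # highest mean -> highest rank
  expect_equal(tbl$rank_ignored, c(2, 2, 2))  # three-way tie -> average rank
  expect_equal(tbl$rank_inflamed, c(1, 2, 3))
  # determinism
  expect_identical(model, build_classifier(expr, ann, c("g1", "g2", "g3")))
  expect_error(build_classifier(expr, ann, c("g1", "nope")), "nope")
})

test_that("assignment is self-consistent, rank-invariant and tie-aware", {
  cohort <- tiny_cohort(seed = 6, n = 10, markers = 5, noise = 50)
  genes <- select_classifier_genes(cohort)
  model <- build_classifier(cohort, genes = genes)

  # centroid means themselves classify to their own phenotype, 1/3 each
  centroids <- dplyr::bind_cols(
    tibble::tibble(gene_id = model$genes$gene_id),
    excluded_c = model$genes$mean_excluded,
    ignored_c = model$genes$mean_ignored,
    inflamed_c = model$genes$mean_inflamed)
  got <- classify_samples(centroids, model)
  expect_equal(got$assigned, phenotype_levels())
  props <- phenotype_proportions(got)
  expect_equal(props$prop, rep(1 / 3, 3))

  # monotone invariance: strictly increasing transforms leave results fixed
  val <- tiny_cohort(seed = 7, n = 5, markers = 5, noise = 50)
  base <- classify_samples(val, model)
  transformed <- val$expression
  transformed[, -1] <- exp(transformed[, -1] / 3) + 100
  expect_equal(classify_samples(transformed, model)$assigned, base$assigned)
  expect_equal(classify_samples(transformed, model)$rho_excluded,
               base$rho_excluded, tolerance = 1e-12)

  # consistent rank-direction flip (descending ranks, negated values)
  flipped <- model
  n <- nrow(flipped$genes)
  for (p in phenotype_levels()) {
    flipped$genes[[paste0("rank_", p)]] <-
      n + 1 - flipped$genes[[paste0("rank_", p)]]
  }
  neg <- val$expression
  neg[, -1] <- -neg[, -1]
  expect_equal(classify_samples(neg, flipped)$assigned, base$assigned)

  # permutation equivariance in gene order
  perm <- sample(nrow(model$genes))
  pmodel <- model
  pmodel$genes <- pmodel$genes[perm, ]
  expect_equal(classify_samples(val, pmodel)$assigned, base$assigned)

  # constant sample: all correlations undefined
  const <- val$expression
  const[[2]] <- 5
  got_const <- classify_samples(const, model)
  expect_equal(got_const$assigned[1], "unassigned")
  expect_equal(got_const$reason[1], "degenerate")
})

test_that("an engineered cohort reproduces 3-of-53 correlation-tie exclusions", {
  # hand-built model with rank vectors (1,2,3,4), (4,3,2,1), (2,1,4,3)
  lab <- rep(phenotype_levels(), each = 2)
  ids <- paste0("s", 1:6)
  vals <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4),
                c(4, 3, 2, 1), c(4, 3, 2, 1),
                c(2, 1, 4, 3), c(2, 1, 4, 3))
  colnames(vals) <- ids
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:4)),
                           tibble::as_tibble(vals))
  ann <- tibble::tibble(sample_id = ids, stained_phenotype = lab)
  model <- build_classifier(expr, ann, genes = paste0("g", 1:4))

  set.seed(8)
  clean <- vapply(sample(phenotype_levels(), 50, replace = TRUE),
                  function(p) model$genes[[paste0("mean_", p)]] +
                    rnorm(4, 0, 0.05),
                  numeric(4))
  tied <- matrix(rep(c(1, 2, 2, 1), 3), ncol = 3) # rho 0 with every centroid
  all_vals <- cbind(clean, tied)
  colnames(all_vals) <- paste0("u", 1:53)
  cohort <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:4)),
                             tibble::as_tibble(all_vals))
  got <- classify_samples(cohort, model)
  expect_equal(sum(got$reason == "correlation_tie"), 3L)
  expect_equal(sum(got$assigned %in% phenotype_levels()), 50L)
})

test_that("low gene coverage yields unassigned with a reason", {
  cohort <- tiny_cohort(seed = 9, n = 15, markers = 5, noise = 20)
  genes <- select_classifier_genes(cohort)
  model <- build_classifier(cohort, genes = genes)
  expr <- cohort$expression
  keep_genes <- model$genes$gene_id[seq_len(floor(nrow(model$genes) * 0.3))]
  sparse <- expr[expr$gene_id %in% keep_genes, ]
  got <- classify_samples(sparse, model)
  expect_true(all(got$assigned == "unassigned"))
  expect_true(all(got$reason == "low_coverage"))
})

test_that("held-out accuracy is high with signal and chance-level without", {
  rep <- run_synthetic_benchmark(seed = 11, n_per_phenotype = 30)
  expect_gte(rep$accuracy, 0.9)

  null_rep <- run_synthetic_benchmark(seed = 12, n_per_phenotype = 100,
                                      effect_size = 0, n_noise_genes = 200)
  expect_true(null_rep$null_cohort)
  n_ok <- sum(null_rep$assignments$assigned %in% phenotype_levels())
  n_correct <- round(null_rep$accuracy * sum(null_rep$confusion))
  bt <- binom.test(n_correct, sum(null_rep$confusion), p = 1 / 3)
  expect_gt(bt$p.value, 0.01)
})
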