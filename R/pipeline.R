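derive_seeds <- function(seed, n) {
  seed <- check_seed(seed)
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Synthetic discovery/validation benchmark of the gene classifier
#'
#' Mirrors the discovery/validation design used to establish the phenotype
#' classifier: simulates two disjoint labelled cohorts, selects classifier
#' genes and builds the rank model on discovery, assigns the validation
#' cohort and reports the 3x3 confusion table with its metrics. With
#' `effect_size = 0` the gene selection is expected to fail (no genes pass);
#' the report then flags the null and falls back to the planted marker genes
#' so that chance-level accuracy can still be measured.
#'
#' @param seed Integer seed; discovery and validation cohorts get
#'   sub-seeds derived from it.
#' @param n_per_phenotype,n_marker_genes,n_noise_genes,effect_size,noise_sd
#'   Passed to [sim_expression_cohort()] for both cohorts.
#' @param logfc_threshold,alpha Passed to [select_classifier_genes()].
#' @return A `benchmark_report` list: `seed`, `config`, `null_cohort` flag,
#'   `selection_error` (message or `NULL`), `genes`, `model`, `assignments`,
#'   `confusion`, `metrics`, `accuracy`, `marker_recall`, `n_unassigned`.
#' @export
#' @examples
#' rep <- run_synthetic_benchmark(seed = 42, n_per_phenotype = 10,
#'                                n_noise_genes = 100)
#' rep$accuracy
run_synthetic_benchmark <- function(seed,
                                    n_per_phenotype = 30,
                                    n_marker_genes = 20,
                                    n_noise_genes = 500,
                                    effect_size = 2,
                                    noise_sd = 1,
                                    logfc_threshold = 1,
                                    alpha = 0.05) {
  seeds <- derive_seeds(seed, 2)
  config <- list(n_per_phenotype = n_per_phenotype,
                 n_marker_genes = n_marker_genes,
                 n_noise_genes = n_noise_genes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 logfc_threshold = logfc_threshold, alpha = alpha)
  discovery <- sim_expression_cohort(
    n_per_phenotype, n_marker_genes, n_noise_genes, effect_size, noise_sd,
    seed = seeds[1], cohort = "discovery", sample_prefix = "D")
  validation <- sim_expression_cohort(
    n_per_phenotype, n_marker_genes, n_noise_genes, effect_size, noise_sd,
    seed = seeds[2], cohort = "validation", sample_prefix = "V")

  planted <- grep("^NOISE_", discovery$expression$gene_id,
                  invert = TRUE, value = TRUE)
  selection_error <- NULL
  genes <- tryCatch(
    select_classifier_genes(discovery, logfc_threshold = logfc_threshold,
                            alpha = alpha),
    error = function(e) {
      selection_error <<- conditionMessage(e)
      NULL
    })
  null_cohort <- is.null(genes)
  if (null_cohort) genes_used <- planted else genes_used <- genes
  model <- build_classifier(discovery, genes = genes_used)

  assignments <- classify_samples(validation, model)
  truth <- validation$annotations$stained_phenotype[
    match(assignments$sample_id, validation$annotations$sample_id)]
  ok <- assignments$assigned %in% phenotype_levels()
  confusion <- suppressMessages(
    confusion_matrix3(truth, assignments$assigned))
  marker_recall <- if (null_cohort) NA_real_ else {
    mean(planted %in% genes$gene_id)
  }
  structure(list(
    seed = seed, config = config,
    null_cohort = null_cohort, selection_error = selection_error,
    genes = genes, model = model, assignments = assignments,
    confusion = confusion, metrics = confusion_metrics(confusion),
    accuracy = accuracy(confusion),
    marker_recall = marker_recall,
    n_unassigned = sum(!ok)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> seed ", x$seed,
      if (x$null_cohort) " (null cohort: gene selection failed)", "\n",
      sep = "")
  print(x$confusion)
  cat("accuracy:", format(x$accuracy, digits = 3),
      " unassigned:", x$n_unassigned, "\n")
  invisible(x)
}

parse_printed <- function(printed) {
  value <- as.numeric(printed)
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^[^.]*\\.", "", printed)), 0L)
  list(value = value, tol = 10^(-dec))
}

#' Recompute the published classifier-performance tables
#'
#' Recomputes every sensitivity, column-precision "specificity", accuracy,
#' NPV and PPV from the transcribed confusion/response tables shipped with
#' the package and asserts agreement with the transcribed published values.
#' Agreement is required to one unit in the last printed decimal: the
#' published tables mix 1- and 2-decimal presentation and at least one entry
#' is truncated rather than rounded, while a single miscounted cell shifts
#' every affected metric by well over that tolerance. The headline accuracy
#' of the primary-cohort table uses the published cohort size as denominator
#' (the table margins sum to one sample fewer; see the package vignette).
#' Any mismatch errors.
#'
#' @param data_dir Directory holding the fixture CSVs (defaults to the
#'   package's `extdata`).
#' @return A `fixture_report` list with the recomputed tables, metrics and a
#'   `comparisons` tibble (`table`, `quantity`, `class`, `published`,
#'   `computed`, `tolerance`, `ok`).
#' @export
#' @examples
#' rep <- run_paper_fixtures()
#' rep$comparisons
run_paper_fixtures <- function(data_dir = system.file("extdata",
                                                      package = "spatialpheno")) {
  path <- function(f) {
    p <- file.path(data_dir, f)
    if (!file.exists(p)) abort_input("fixture missing: ", p)
    p
  }
  read_cm <- function(f) {
    tab <- readr::read_csv(path(f), show_col_types = FALSE)
    as_confusion_matrix3(as.matrix(tab[, phenotype_levels()]))
  }
  cm1 <- read_cm("table1_primary_confusion.csv")
  cm2 <- read_cm("table2_lnmet_confusion.csv")
  t3raw <- readr::read_csv(path("table3_response_counts.csv"),
                           show_col_types = FALSE)
  t3 <- as_two_by_two(as.matrix(t3raw[, c("nonresponder", "responder")]))
  published <- readr::read_csv(path("published_performance.csv"),
                               col_types = "cccc")

  cohort_n <- function(tab) {
    row <- published[published$table == tab & published$quantity == "cohort_n", ]
    if (nrow(row)) as.numeric(row$printed) else NULL
  }
  met <- list(table1 = confusion_metrics(cm1), table2 = confusion_metrics(cm2))
  acc <- c(table1 = accuracy(cm1, n_total = cohort_n("table1")),
           table2 = accuracy(cm2, n_total = cohort_n("table2")))
  pv <- npv_ppv(t3)

  computed_value <- function(tab, quantity, class) {
    if (quantity %in% c("sensitivity", "specificity_paper")) {
      m <- met[[tab]]
      return(m[[quantity]][m$phenotype == class])
    }
    switch(quantity,
           accuracy = unname(acc[tab]),
           npv = pv$npv,
           ppv = pv$ppv,
           abort_input("unknown published quantity: ", quantity))
  }
  rows <- published[published$quantity != "cohort_n", ]
  parsed <- parse_printed(rows$printed)
  computed <- purrr::pmap_dbl(
    list(rows$table, rows$quantity, rows$class),
    function(tab, quantity, class) computed_value(tab, quantity, class))
  comparisons <- tibble::tibble(
    table = rows$table, quantity = rows$quantity, class = rows$class,
    published = parsed$value, computed = computed,
    tolerance = parsed$tol,
    ok = abs(computed - parsed$value) <= parsed$tol
  )
  if (!all(comparisons$ok)) {
    bad <- comparisons[!comparisons$ok, ]
    abort_input("recomputed metrics disagree with the published tables: ",
                paste(sprintf("%s %s %s (computed %.4f vs published %s)",
                              bad$table, bad$quantity, bad$class,
                              bad$computed, format(bad$published)),
                      collapse = "; "))
  }
  structure(list(
    table1 = list(confusion = cm1, metrics = met$table1,
                  accuracy = unname(acc["table1"])),
    table2 = list(confusion = cm2, metrics = met$table2,
                  accuracy = unname(acc["table2"])),
    table3 = list(counts = t3, predictive_values = pv,
                  odds_ratio = odds_ratio_2x2(t3)),
    comparisons = comparisons
  ), class = "fixture_report")
}

#' @export
print.fixture_report <- function(x, ...) {
  cat("<fixture_report> all ", nrow(x$comparisons),
      " published values reproduced\n", sep = "")
  cat("primary accuracy ", format(x$table1$accuracy, digits = 3),
      ", LN-metastasis accuracy ", format(x$table2$accuracy, digits = 3),
      ", NPV ", format(x$table3$predictive_values$npv, digits = 3),
      ", PPV ", format(x$table3$predictive_values$ppv, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' End-to-end anti-PD1 response experiment on synthetic data
#'
#' Simulates the full clinical-evaluation chain: a labelled discovery cohort
#' trains the classifier; an independent cohort receives phenotype-dependent
#' response labels (defaults: the observed trial rates of 6/10 responders in
#' inflamed and 4/39 in excluded+ignored); phenotypes are then assigned by
#' the classifier and the response table, NPV/PPV, odds ratio and gene-set
#' ROC curves are computed on the *assigned* labels. As the simulated cohort
#' grows, NPV and PPV converge toward the generating rates (35/39 and 0.6)
#' up to the classifier's misassignment rate.
#'
#' @param seed Integer seed.
#' @param n_per_phenotype Samples per phenotype in the evaluation cohort
#'   (default 1000, i.e. 3000 samples).
#' @param discovery_n Samples per phenotype in the discovery cohort
#'   (default 30).
#' @param p_response Named response probabilities per phenotype (defaults to
#'   the trial rates).
#' @param effect_size,noise_sd,n_marker_genes,n_noise_genes Simulation
#'   parameters shared by both cohorts.
#' @return A `response_report` list: `counts` (2x2 table on assigned
#'   phenotypes), `predictive_values`, `odds_ratio` (IRLS fit tibble),
#'   `odds_ratio_2x2`, `roc_inflamed`, `roc_excluded`,
#'   `assignment_accuracy`, `n_unassigned`, `seed`.
#' @export
run_response_experiment <- function(seed,
                                    n_per_phenotype = 1000,
                                    discovery_n = 30,
                                    p_response = c(excluded = 4 / 39,
                                                   ignored = 4 / 39,
                                                   inflamed = 6 / 10),
                                    effect_size = 2, noise_sd = 1,
                                    n_marker_genes = 20, n_noise_genes = 500) {
  seeds <- derive_seeds(seed, 3)
  discovery <- sim_expression_cohort(
    discovery_n, n_marker_genes, n_noise_genes, effect_size, noise_sd,
    seed = seeds[1], cohort = "discovery", sample_prefix = "D")
  cohort <- sim_expression_cohort(
    n_per_phenotype, n_marker_genes, n_noise_genes, effect_size, noise_sd,
    seed = seeds[2], cohort = "trial", sample_prefix = "T")
  cohort <- sim_response_labels(cohort, p_response, seed = seeds[3])

  genes <- select_classifier_genes(discovery)
  model <- build_classifier(discovery, genes = genes)
  assignments <- classify_samples(cohort, model)

  ann <- dplyr::left_join(assignments, cohort$annotations, by = "sample_id")
  counts <- suppressMessages(response_table(ann$assigned, ann$response))
  ok <- ann$assigned %in% phenotype_levels()
  or_fit <- logistic_or(as.numeric(ann$assigned[ok] == "inflamed"),
                        ann$response[ok])

  sets <- split(model$genes$gene_id, model$genes$signature_phenotype)
  infl_score <- gene_set_score(cohort, sets$inflamed)
  excl_score <- gene_set_score(cohort, sets$excluded)
  resp <- cohort$annotations$response[
    match(infl_score$sample_id, cohort$annotations$sample_id)]
  roc_inflamed <- roc_auc(infl_score$score, resp, direction = "higher")
  roc_excluded <- roc_auc(excl_score$score, resp, direction = "lower")

  structure(list(
    seed = seed,
    counts = counts,
    predictive_values = npv_ppv(counts),
    odds_ratio = or_fit,
    odds_ratio_2x2 = odds_ratio_2x2(counts),
    roc_inflamed = roc_inflamed,
    roc_excluded = roc_excluded,
    assignment_accuracy = mean(
      ann$assigned[ok] == ann$stained_phenotype[ok]),
    n_unassigned = sum(!ok)
  ), class = "response_report")
}

#' @export
print.response_report <- function(x, ...) {
  pv <- x$predictive_values
  cat("<response_report> NPV ", format(pv$npv, digits = 3),
      "  PPV ", format(pv$ppv, digits = 3),
      "  OR ", format(x$odds_ratio$odds_ratio, digits = 3),
      "  inflamed-set AUC ", format(x$roc_inflamed$auc, digits = 3), "\n",
      sep = "")
  invisible(x)
}
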