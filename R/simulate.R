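#' Archetype CD8 stamp intensities per spatial phenotype
#'
#' Default border/center CD8+ T cell intensities (cells/mm^2) used by
#' [sim_cell_pattern()]. They place each archetype safely inside its own
#' decision region of the digital threshold rule (border > 200 cells/mm^2 with
#' a border:center ratio below/above 10 for inflamed/excluded; both regions
#' below 150 cells/mm^2 for ignored), so that threshold assignment recovers
#' the generating phenotype.
#'
#' @format A tibble with columns `phenotype`, `marker`, `border`, `center`
#'   (intensities in cells/mm^2).
#' @export
phenotype_archetypes <- tibble::tibble(
  phenotype = c("excluded", "ignored", "inflamed"),
  marker    = "CD8",
  border    = c(400, 50, 400),
  center    = c(10, 30, 300)
)

demo_marker_genes <- list(
  excluded = c("COL10A1", "THBS2", "ASPN", "COL5A1", "GREM1", "SPON1", "FAP",
               "SPOCK1"),
  ignored  = c("S100A7"),
  inflamed = c("CXCL13", "CCL5", "GZMB", "WARS", "TRBC1", "CORO1A", "CCL18",
               "IL2RG", "NKG7", "IGHG1")
)

new_expression_cohort <- function(expression, annotations) {
  structure(list(expression = expression, annotations = annotations),
            class = "expression_cohort")
}

#' Simulate a phenotype-labelled log2 expression cohort
#'
#' Generates a balanced cohort of `3 * n_per_phenotype` samples with
#' per-phenotype marker genes: each phenotype owns `n_marker_genes` genes whose
#' mean is `baseline + effect_size` (log2 units) in that phenotype and
#' `baseline` elsewhere; `n_noise_genes` genes share the baseline mean in all
#' phenotypes. Values are mean + Gaussian noise with standard deviation
#' `noise_sd` on the log2 scale. Only differences between group means matter to
#' the downstream rank-based classifier, hence the flat baseline.
#'
#' @param n_per_phenotype Samples per phenotype (default 30).
#' @param n_marker_genes Marker genes per phenotype (default 20).
#' @param n_noise_genes Genes with no phenotype effect (default 500).
#' @param effect_size Log2 fold-change of a marker gene in its own phenotype
#'   (default 2; 0 gives a null cohort).
#' @param noise_sd Gaussian noise standard deviation, log2 scale (default 1).
#' @param baseline Baseline log2 expression for all genes (default 5).
#' @param seed Integer seed; required, the generator never touches global RNG
#'   state.
#' @param cohort Cohort tag stored in the annotations.
#' @param sample_prefix Prefix for generated sample ids.
#' @param label_demo_genes If `TRUE`, relabel the first marker genes of each
#'   phenotype with illustrative human gene symbols (collagen/matrix genes for
#'   excluded, `S100A7` for ignored, cytotoxicity/chemokine genes for
#'   inflamed). For demos only; has no effect on the simulation.
#' @return An `expression_cohort`: a list with `$expression` (tibble,
#'   `gene_id` + one column per sample) and `$annotations` (tibble with
#'   `sample_id`, `stained_phenotype`, `cohort`).
#' @export
#' @examples
#' cohort <- sim_expression_cohort(n_per_phenotype = 5, n_marker_genes = 3,
#'                                 n_noise_genes = 10, seed = 1)
#' dim(cohort$expression)
#' dplyr::count(cohort$annotations, stained_phenotype)
sim_expression_cohort <- function(n_per_phenotype = 30,
                                  n_marker_genes = 20,
                                  n_noise_genes = 500,
                                  effect_size = 2,
                                  noise_sd = 1,
                                  baseline = 5,
                                  seed,
                                  cohort = "synthetic",
                                  sample_prefix = "S",
                                  label_demo_genes = FALSE) {
  n_per_phenotype <- check_count(n_per_phenotype, "n_per_phenotype", min = 1L)
  n_marker_genes <- check_count(n_marker_genes, "n_marker_genes", min = 1L)
  n_noise_genes <- check_count(n_noise_genes, "n_noise_genes", min = 0L)
  check_number(effect_size, "effect_size", min = 0)
  check_number(noise_sd, "noise_sd", min = 0, allow_min = FALSE)
  seed <- check_seed(seed)

  phen <- phenotype_levels()
  prefixes <- c(excluded = "EXC", ignored = "IGN", inflamed = "INF")
  marker_ids <- lapply(phen, function(p) {
    ids <- sprintf("%s_%03d", prefixes[[p]], seq_len(n_marker_genes))
    if (label_demo_genes) {
      demo <- demo_marker_genes[[p]]
      k <- min(length(demo), n_marker_genes)
      ids[seq_len(k)] <- demo[seq_len(k)]
    }
    ids
  })
  names(marker_ids) <- phen
  gene_ids <- c(unlist(marker_ids, use.names = FALSE),
                if (n_noise_genes > 0) sprintf("NOISE_%04d", seq_len(n_noise_genes)))

  n_genes <- length(gene_ids)
  n_samples <- 3L * n_per_phenotype
  sample_ids <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  labels <- rep(phen, each = n_per_phenotype)

  mu <- matrix(baseline, nrow = n_genes, ncol = n_samples)
  for (k in seq_along(phen)) {
    rows <- (k - 1L) * n_marker_genes + seq_len(n_marker_genes)
    mu[rows, labels == phen[k]] <- baseline + effect_size
  }
  values <- withr::with_seed(seed, {
    mu + matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
  })
  colnames(values) <- sample_ids

  expression <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                                 tibble::as_tibble(values))
  annotations <- tibble::tibble(sample_id = sample_ids,
                                stained_phenotype = labels,
                                cohort = cohort)
  new_expression_cohort(expression, annotations)
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", nrow(x$expression), " genes x ",
      ncol(x$expression) - 1L, " samples\n", sep = "")
  print(dplyr::count(x$annotations, .data$stained_phenotype))
  invisible(x)
}

#' @describeIn sim_expression_cohort Long-format view of a cohort: one row per
#'   gene x sample with its log2 value and the stained phenotype.
#' @param x An `expression_cohort`.
#' @param ... Unused.
#' @export
tidy.expression_cohort <- function(x, ...) {
  long <- tidyr::pivot_longer(x$expression, -"gene_id",
                              names_to = "sample_id", values_to = "log2_expr")
  dplyr::left_join(long, x$annotations, by = "sample_id")
}

#' Simulate a stamp-based cell point pattern for one sample
#'
#' Draws a homogeneous Poisson point pattern per marker per stamp: the cell
#' count in each 670 x 502 um stamp is Poisson with mean
#' `intensity * stamp area (mm^2)` and coordinates are uniform within the
#' stamp. Stamps are disjoint fields of view with a local origin at the
#' lower-left corner; no distances are defined across stamps. Each cell is
#' labelled tumor or stroma independently with probability `p_tumor`.
#'
#' @param phenotype Archetype whose default CD8 intensities to use; one of
#'   [phenotype_levels()].
#' @param n_stamps_border,n_stamps_center Stamps per region (default 8 each).
#' @param intensities Optional tibble with columns `marker`, `border`,
#'   `center` (cells/mm^2); defaults to the CD8 row of
#'   [phenotype_archetypes] for `phenotype`.
#' @param geometry A [stamp_geometry()].
#' @param p_tumor Probability a cell lies in the tumor (vs stroma)
#'   compartment.
#' @param seed Integer seed; required.
#' @param sample_id Sample id written into the table.
#' @return A cell table tibble with columns `sample_id`, `stamp_id`, `region`,
#'   `compartment`, `marker`, `x_um`, `y_um`.
#' @export
#' @examples
#' cells <- sim_cell_pattern("inflamed", seed = 7)
#' dplyr::count(cells, region)
sim_cell_pattern <- function(phenotype = c("inflamed", "excluded", "ignored"),
                             n_stamps_border = 8,
                             n_stamps_center = 8,
                             intensities = NULL,
                             geometry = stamp_geometry(),
                             p_tumor = 0.5,
                             seed,
                             sample_id = NULL) {
  phenotype <- match.arg(phenotype)
  n_stamps_border <- check_count(n_stamps_border, "n_stamps_border", min = 1L)
  n_stamps_center <- check_count(n_stamps_center, "n_stamps_center", min = 1L)
  check_number(p_tumor, "p_tumor", min = 0, max = 1)
  seed <- check_seed(seed)
  sample_id <- sample_id %||% paste0(phenotype, "_01")

  if (is.null(intensities)) {
    intensities <- phenotype_archetypes[phenotype_archetypes$phenotype == phenotype,
                                        c("marker", "border", "center")]
  }
  check_columns(intensities, c("marker", "border", "center"), "intensities")
  if (any(intensities$border < 0) || any(intensities$center < 0)) {
    abort_input("intensities must be >= 0 cells/mm^2")
  }

  stamps <- dplyr::bind_rows(
    tibble::tibble(region = "border",
                   stamp_id = sprintf("B%02d", seq_len(n_stamps_border))),
    tibble::tibble(region = "center",
                   stamp_id = sprintf("C%02d", seq_len(n_stamps_center)))
  )
  cfg <- tidyr::pivot_longer(intensities, c("border", "center"),
                             names_to = "region", values_to = "intensity")
  grid <- dplyr::inner_join(stamps, cfg, by = "region",
                            relationship = "many-to-many")

  cells <- withr::with_seed(seed, {
    n <- rpois(nrow(grid), grid$intensity * geometry$area_mm2)
    total <- sum(n)
    tibble::tibble(
      sample_id = if (total > 0) sample_id else character(0),
      stamp_id = rep(grid$stamp_id, n),
      region = rep(grid$region, n),
      compartment = ifelse(runif(total) < p_tumor, "tumor", "stroma"),
      marker = rep(grid$marker, n),
      x_um = runif(total, 0, geometry$width_um),
      y_um = runif(total, 0, geometry$height_um)
    )
  })
  # declare the stamp layout so empty stamps are not lost downstream
  attr(cells, "stamps") <- tibble::tibble(
    sample_id = sample_id,
    region = c("border", "center"),
    n_stamps = c(n_stamps_border, n_stamps_center))
  cells
}

#' Simulate a clonally structured TCR repertoire
#'
#' Clonotype proportions are drawn from a symmetric Dirichlet distribution
#' with the given concentration (small values give clonally skewed
#' repertoires, large values approach a uniform repertoire) and read counts
#' from a multinomial with `total_reads` draws. Clonotypes that receive zero
#' reads are dropped with a message. Each clonotype gets a synthetic CDR3
#' amino-acid string.
#'
#' @param n_clonotypes Number of clonotypes drawn (>= 1).
#' @param total_reads Total read count distributed across clonotypes
#'   (>= `n_clonotypes`).
#' @param concentration Symmetric Dirichlet concentration (> 0); 1 is neutral,
#'   0.05 strongly skewed, 1e6 effectively uniform.
#' @param seed Integer seed; required.
#' @return Tibble with columns `clonotype_id`, `cdr3_aa`, `count`
#'   (all counts >= 1).
#' @export
#' @examples
#' rep <- sim_tcr_repertoire(50, 5000, concentration = 0.1, seed = 3)
#' gini_simpson(rep$count)
sim_tcr_repertoire <- function(n_clonotypes, total_reads, concentration = 1,
                               seed) {
  n_clonotypes <- check_count(n_clonotypes, "n_clonotypes", min = 1L)
  total_reads <- check_count(total_reads, "total_reads", min = n_clonotypes)
  check_number(concentration, "concentration", min = 0, allow_min = FALSE)
  seed <- check_seed(seed)

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- withr::with_seed(seed, {
    g <- rgamma(n_clonotypes, shape = concentration, rate = 1)
    if (sum(g) == 0) g <- rep(1, n_clonotypes) # gamma underflow at tiny shape
    counts <- as.vector(rmultinom(1, total_reads, g / sum(g)))
    mids <- vapply(sample(4:8, n_clonotypes, replace = TRUE),
                   function(k) paste(sample(aa, k, replace = TRUE), collapse = ""),
                   character(1))
    list(counts = counts, cdr3 = paste0("CASS", mids, "QYF"))
  })
  rep_tbl <- tibble::tibble(
    clonotype_id = sprintf("CL%05d", seq_len(n_clonotypes)),
    cdr3_aa = out$cdr3,
    count = out$counts
  )
  dropped <- sum(rep_tbl$count == 0)
  if (dropped > 0) {
    message("dropped ", dropped, " clonotype(s) with zero sampled reads")
  }
  rep_tbl[rep_tbl$count >= 1, ]
}

#' Attach anti-PD1 response labels to an annotated cohort
#'
#' Adds a `response` column (`responder` / `nonresponder`) to per-sample
#' annotations by an independent Bernoulli draw with a phenotype-specific
#' response probability. Defaults reflect the response rates observed under
#' anti-PD1 in metastatic TNBC: 6/10 for the inflamed phenotype and 4/39 for
#' the excluded and ignored phenotypes combined.
#'
#' @param annotations Annotation tibble with `sample_id` and
#'   `stained_phenotype`, or an `expression_cohort` (its annotations are
#'   updated in place).
#' @param p_response Named probabilities of response per phenotype.
#' @param seed Integer seed; required.
#' @return The annotations tibble (or cohort) with a `response` column.
#' @export
#' @examples
#' cohort <- sim_expression_cohort(n_per_phenotype = 5, n_marker_genes = 2,
#'                                 n_noise_genes = 5, seed = 1)
#' ann <- sim_response_labels(cohort$annotations, seed = 2)
#' table(ann$stained_phenotype, ann$response)
sim_response_labels <- function(annotations,
                                p_response = c(excluded = 4 / 39,
                                               ignored = 4 / 39,
                                               inflamed = 6 / 10),
                                seed) {
  seed <- check_seed(seed)
  if (inherits(annotations, "expression_cohort")) {
    annotations$annotations <-
      sim_response_labels(annotations$annotations, p_response, seed)
    return(annotations)
  }
  check_columns(annotations, c("sample_id", "stained_phenotype"), "annotations")
  if (anyNA(annotations$stained_phenotype)) {
    abort_input("all samples need a `stained_phenotype` to draw response labels")
  }
  if (any(p_response < 0 | p_response > 1)) {
    abort_input("`p_response` probabilities must lie in [0, 1]")
  }
  need <- unique(annotations$stained_phenotype)
  miss <- setdiff(need, names(p_response))
  if (length(miss)) {
    abort_input("`p_response` missing phenotype(s): ", paste(miss, collapse = ", "))
  }
  p <- unname(p_response[annotations$stained_phenotype])
  annotations$response <- withr::with_seed(seed, {
    ifelse(runif(nrow(annotations)) < p, "responder", "nonresponder")
  })
  annotations
}
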