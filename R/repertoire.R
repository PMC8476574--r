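#' Gini-Simpson index of clonal skewness
#'
#' `1 - sum(p_i^2)` over clonotype read proportions: 0 for a monoclonal
#' repertoire, approaching `1 - 1/K` for `K` evenly represented clonotypes.
#' Invariant under uniform scaling of the counts. The optional small-sample
#' bias correction uses the unbiased estimator
#' `1 - sum(c_i * (c_i - 1)) / (N * (N - 1))`.
#'
#' @param counts Positive read counts per clonotype (zero counts are
#'   dropped).
#' @param bias_correction Apply the unbiased finite-sample estimator
#'   (default `FALSE`, plain plug-in index).
#' @return Index in `[0, 1)`.
#' @export
#' @examples
#' gini_simpson(c(9, 1)) # 1 - (0.81 + 0.01) = 0.18
gini_simpson <- function(counts, bias_correction = FALSE) {
  if (!is.numeric(counts)) abort_input("`counts` must be numeric")
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0L) abort_input("empty repertoire")
  n <- sum(counts)
  if (bias_correction) {
    if (n < 2) abort_input("bias correction needs >= 2 reads")
    return(1 - sum(counts * (counts - 1)) / (n * (n - 1)))
  }
  1 - sum((counts / n)^2)
}

#' Number of distinct clonotypes
#'
#' The count of clonotypes with at least one read -- the repertoire-diversity
#' axis reported alongside skewness. (The total read count is a separate
#' field of [tcr_metrics()].)
#'
#' @param counts Read counts per clonotype.
#' @return Integer count; 0 with a warning for an empty repertoire.
#' @export
tcr_diversity <- function(counts) {
  if (!is.numeric(counts)) abort_input("`counts` must be numeric")
  counts <- counts[!is.na(counts)]
  n <- sum(counts >= 1)
  if (n == 0L) warning("empty repertoire")
  as.integer(n)
}

#' Repertoire summary metrics
#'
#' One-row summary of a clonotype count table: distinct clonotypes, total
#' reads, Gini-Simpson skewness (plain and bias-corrected) and the largest
#' clone's read fraction.
#'
#' @param repertoire Tibble with a `count` column (e.g. from
#'   [sim_tcr_repertoire()] or [read_repertoire()]).
#' @return One-row tibble `n_clonotypes`, `total_reads`, `gini_simpson`,
#'   `gini_simpson_corrected`, `max_clone_fraction`.
#' @export
#' @examples
#' tcr_metrics(sim_tcr_repertoire(100, 1e4, concentration = 0.2, seed = 1))
tcr_metrics <- function(repertoire) {
  check_columns(repertoire, "count", "repertoire")
  counts <- repertoire$count
  tibble::tibble(
    n_clonotypes = tcr_diversity(counts),
    total_reads = sum(counts),
    gini_simpson = gini_simpson(counts),
    gini_simpson_corrected = if (sum(counts) >= 2) {
      gini_simpson(counts, bias_correction = TRUE)
    } else NA_real_,
    max_clone_fraction = max(counts) / sum(counts)
  )
}
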