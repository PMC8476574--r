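#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-rank-transformed vectors; the convention
#' fixed for the phenotype classifier (rank-vs-rank and value-vs-rank are
#' equivalent under this transform).
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either vector is
#'   constant after ranking (zero variance).
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)) # 0.6
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_input("`x` and `y` must have equal length")
  if (length(x) < 3L) abort_input("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_input("`x` and `y` must be finite")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- rx - mean(rx)
  sy <- ry - mean(ry)
  vx <- sum(sx^2)
  vy <- sum(sy^2)
  if (vx == 0 || vy == 0) {
    warning("zero variance after ranking; correlation undefined")
    return(NA_real_)
  }
  sum(sx * sy) / sqrt(vx * vy)
}

# Vectorized Welch two-sample t-test over the rows of two matrices.
welch_rows <- function(m1, m2) {
  n1 <- ncol(m1)
  n2 <- ncol(m2)
  mu1 <- rowMeans(m1)
  mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate zero-variance rows: identical groups -> p 1, separated -> p 0
  bad <- !is.finite(tstat)
  p[bad] <- ifelse(mu1[bad] == mu2[bad], 1, 0)
  list(logfc = mu1 - mu2, t = tstat, df = df, p = p)
}

#' Select phenotype-signature genes by differential expression
#'
#' A gene becomes a classifier gene with signature phenotype `p` when its mean
#' log2 expression in `p` exceeds its mean in *each* other phenotype by more
#' than `logfc_threshold` and both pairwise Welch two-sample tests are
#' significant after Benjamini-Hochberg adjustment (applied per contrast
#' across all genes). This all-pairwise rule yields mutually exclusive gene
#' blocks; a one-vs-rest alternative is available via `contrast`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns, log2 scale) or
#'   an `expression_cohort`.
#' @param annotations Annotation tibble with `sample_id` and
#'   `stained_phenotype` (ignored when `expr` is a cohort).
#' @param logfc_threshold Minimum log2 fold-change over each other phenotype
#'   (default 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_genes_per_phenotype Fail unless every phenotype retains at least
#'   this many genes (default 1).
#' @param contrast `"all_pairwise"` (default) or `"one_vs_rest"`.
#' @return Tibble `gene_id`, `signature_phenotype`, `logfc_min` (smallest
#'   margin over the other phenotypes, or over the rest), `padj_max` (largest
#'   adjusted p among the tests backing the call).
#' @export
select_classifier_genes <- function(expr, annotations = NULL,
                                    logfc_threshold = 1, alpha = 0.05,
                                    min_genes_per_phenotype = 1,
                                    contrast = c("all_pairwise", "one_vs_rest")) {
  contrast <- match.arg(contrast)
  check_number(logfc_threshold, "logfc_threshold", min = 0, allow_min = FALSE)
  check_number(alpha, "alpha", min = 0, max = 1, allow_min = FALSE)
  if (inherits(expr, "expression_cohort")) {
    annotations <- expr$annotations
    expr <- expr$expression
  }
  m <- expr_matrix(expr)
  labels <- aligned_labels(m, annotations)
  if (anyNA(labels)) abort_input("all samples need a stained phenotype label")
  phen <- phenotype_levels()
  n_by <- table(factor(labels, levels = phen))
  if (any(n_by < 2L)) {
    abort_input("need >= 2 samples per phenotype; got ",
                paste(paste0(phen, "=", as.integer(n_by)), collapse = ", "))
  }
  groups <- lapply(phen, function(p) m[, labels == p, drop = FALSE])
  names(groups) <- phen

  if (contrast == "all_pairwise") {
    pairs <- utils::combn(phen, 2, simplify = FALSE)
    tests <- lapply(pairs, function(pr) {
      w <- welch_rows(groups[[pr[1]]], groups[[pr[2]]])
      w$padj <- bh_adjust(w$p)
      w
    })
    names(tests) <- vapply(pairs, paste, "", collapse = ".")
    sel <- lapply(phen, function(p) {
      others <- setdiff(phen, p)
      lfc <- vapply(others, function(q) {
        key <- paste(sort(c(p, q)), collapse = ".")
        s <- if (p < q) 1 else -1
        s * tests[[key]]$logfc
      }, numeric(nrow(m)))
      padj <- vapply(others, function(q) {
        tests[[paste(sort(c(p, q)), collapse = ".")]]$padj
      }, numeric(nrow(m)))
      lfc <- matrix(lfc, nrow = nrow(m))
      padj <- matrix(padj, nrow = nrow(m))
      hit <- rowSums(lfc > logfc_threshold) == 2L & rowSums(padj < alpha) == 2L
      tibble::tibble(gene_id = rownames(m)[hit],
                     signature_phenotype = p,
                     logfc_min = apply(lfc[hit, , drop = FALSE], 1, min),
                     padj_max = apply(padj[hit, , drop = FALSE], 1, max))
    })
  } else {
    sel <- lapply(phen, function(p) {
      w <- welch_rows(groups[[p]],
                      m[, labels != p, drop = FALSE])
      padj <- bh_adjust(w$p)
      hit <- w$logfc > logfc_threshold & padj < alpha
      tibble::tibble(gene_id = rownames(m)[hit],
                     signature_phenotype = p,
                     logfc_min = w$logfc[hit],
                     padj_max = padj[hit])
    })
  }
  out <- dplyr::bind_rows(sel)
  if (contrast == "one_vs_rest" && anyDuplicated(out$gene_id)) {
    out <- dplyr::slice_max(dplyr::group_by(out, .data$gene_id),
                            .data$logfc_min, n = 1, with_ties = FALSE)
    out <- dplyr::ungroup(out)
  }
  n_sel <- table(factor(out$signature_phenotype, levels = phen))
  if (nrow(out) == 0L || any(n_sel < min_genes_per_phenotype)) {
    abort_input("gene selection failed: ",
                paste(paste0(phen, "=", as.integer(n_sel)), collapse = ", "),
                " genes passed (need >= ", min_genes_per_phenotype,
                " per phenotype)")
  }
  dplyr::arrange(out, .data$signature_phenotype, dplyr::desc(.data$logfc_min))
}

#' Build the nearest-centroid rank classifier
#'
#' Averages each classifier gene's log2 expression over the samples of each
#' phenotype (centroid means) and ranks those means within each phenotype's
#' centroid vector, ascending (highest expression gets the highest rank,
#' ties share the average rank). Unknown samples are later compared against
#' these three rank vectors by Spearman correlation.
#'
#' @inheritParams select_classifier_genes
#' @param genes Output of [select_classifier_genes()] (tibble with `gene_id`
#'   and `signature_phenotype`) or a bare character vector of gene ids (the
#'   signature phenotype is then taken as the arg-max centroid).
#' @return A `spatial_classifier` object; see [tidy.spatial_classifier()].
#' @export
#' @examples
#' cohort <- sim_expression_cohort(n_per_phenotype = 10, n_marker_genes = 5,
#'                                 n_noise_genes = 50, seed = 1)
#' genes <- select_classifier_genes(cohort)
#' model <- build_classifier(cohort, genes = genes)
#' model
build_classifier <- function(expr, annotations = NULL, genes) {
  if (inherits(expr, "expression_cohort")) {
    annotations <- expr$annotations
    expr <- expr$expression
  }
  if (is.character(genes)) {
    genes <- tibble::tibble(gene_id = genes,
                            signature_phenotype = NA_character_)
  }
  check_columns(genes, c("gene_id", "signature_phenotype"), "genes")
  m <- expr_matrix(expr)
  missing_genes <- setdiff(genes$gene_id, rownames(m))
  if (length(missing_genes)) {
    abort_input("gene(s) absent from `expr`: ",
                paste(head(missing_genes, 5), collapse = ", "))
  }
  labels <- aligned_labels(m, annotations)
  phen <- phenotype_levels()
  m <- m[genes$gene_id, , drop = FALSE]
  means <- vapply(phen, function(p) rowMeans(m[, labels == p, drop = FALSE]),
                  numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m), dimnames = list(genes$gene_id, phen))
  ranks <- apply(means, 2, rank, ties.method = "average")
  ranks <- matrix(ranks, nrow = nrow(m), dimnames = dimnames(means))

  sig <- genes$signature_phenotype
  if (anyNA(sig)) {
    sig[is.na(sig)] <- phen[max.col(means[is.na(sig), , drop = FALSE],
                                    ties.method = "first")]
  }

  tbl <- tibble::tibble(
    gene_id = genes$gene_id,
    signature_phenotype = unname(sig),
    mean_excluded = unname(means[, "excluded"]),
    mean_ignored = unname(means[, "ignored"]),
    mean_inflamed = unname(means[, "inflamed"]),
    rank_excluded = unname(ranks[, "excluded"]),
    rank_ignored = unname(ranks[, "ignored"]),
    rank_inflamed = unname(ranks[, "inflamed"])
  )
  structure(list(genes = tbl, phenotypes = phen),
            class = "spatial_classifier")
}

#' @export
print.spatial_classifier <- function(x, ...) {
  cat("<spatial_classifier> ", nrow(x$genes), " genes\n", sep = "")
  print(table(x$genes$signature_phenotype))
  invisible(x)
}

#' Tidy / glance methods for spatial classifiers
#'
#' `tidy()` returns the per-gene table (signature phenotype, per-phenotype
#' centroid means and ranks, mirroring the published classifier-gene
#' supplement); `glance()` a one-row summary.
#'
#' @param x A `spatial_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spatial_classifier <- function(x, ...) x$genes

#' @rdname tidy.spatial_classifier
#' @export
glance.spatial_classifier <- function(x, ...) {
  tab <- table(factor(x$genes$signature_phenotype,
                      levels = phenotype_levels()))
  tibble::tibble(n_genes = nrow(x$genes),
                 n_excluded = as.integer(tab[["excluded"]]),
                 n_ignored = as.integer(tab[["ignored"]]),
                 n_inflamed = as.integer(tab[["inflamed"]]))
}

rank_matrix <- function(model) {
  r <- as.matrix(model$genes[, paste0("rank_", model$phenotypes)])
  colnames(r) <- model$phenotypes
  rownames(r) <- model$genes$gene_id
  r
}

#' Assign spatial phenotypes to unknown samples
#'
#' Each sample's values over the classifier genes are Spearman-correlated
#' with the three phenotype centroid rank vectors; the sample is assigned the
#' arg-max phenotype. Being rank-based, assignments are invariant under any
#' strictly increasing transform of a sample's values. Genes missing from
#' `expr` (or `NA` in a sample) are dropped pairwise; a sample retaining
#' fewer than `min_coverage` of the classifier genes is `unassigned`
#' (`low_coverage`), as is a sample whose top two correlations differ by at
#' most `tie_epsilon` (`correlation_tie`) or whose correlations are all
#' undefined (`degenerate`).
#'
#' @param expr Expression tibble or `expression_cohort` with the samples to
#'   classify.
#' @param model A [build_classifier()] result.
#' @param tie_epsilon Correlation difference at or below which the top two
#'   phenotypes are a tie (default 1e-12, i.e. exact ties).
#' @param min_coverage Minimum fraction of classifier genes with values
#'   (default 0.5).
#' @return Tibble `sample_id`, `rho_excluded`, `rho_ignored`, `rho_inflamed`,
#'   `assigned`, `reason`.
#' @export
classify_samples <- function(expr, model, tie_epsilon = 1e-12,
                             min_coverage = 0.5) {
  if (!inherits(model, "spatial_classifier")) {
    abort_input("`model` must be a spatial_classifier")
  }
  check_number(tie_epsilon, "tie_epsilon", min = 0)
  check_number(min_coverage, "min_coverage", min = 0, max = 1)
  if (inherits(expr, "expression_cohort")) expr <- expr$expression
  m <- expr_matrix(expr)
  genes <- model$genes$gene_id
  v <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
              dimnames = list(genes, colnames(m)))
  present <- intersect(genes, rownames(m))
  v[present, ] <- m[present, , drop = FALSE]
  ranks <- rank_matrix(model)
  phen <- model$phenotypes

  one <- function(j) {
    x <- v[, j]
    keep <- is.finite(x)
    coverage <- mean(keep)
    rho <- rep(NA_real_, length(phen))
    if (coverage < min_coverage || sum(keep) < 3L) {
      return(list(rho = rho, assigned = "unassigned", reason = "low_coverage"))
    }
    rho <- vapply(phen, function(p) {
      suppressWarnings(spearman_rho(x[keep], ranks[keep, p]))
    }, numeric(1))
    if (all(is.na(rho))) {
      return(list(rho = rho, assigned = "unassigned", reason = "degenerate"))
    }
    ord <- order(rho, decreasing = TRUE, na.last = TRUE)
    top <- rho[ord[1]]
    second <- if (length(ord) > 1L) rho[ord[2]] else NA_real_
    if (!is.na(second) && (top - second) <= tie_epsilon) {
      return(list(rho = rho, assigned = "unassigned",
                  reason = "correlation_tie"))
    }
    list(rho = rho, assigned = phen[ord[1]], reason = "ok")
  }
  res <- lapply(seq_len(ncol(v)), one)
  rho <- do.call(rbind, lapply(res, `[[`, "rho"))
  tibble::tibble(
    sample_id = colnames(v),
    rho_excluded = rho[, 1],
    rho_ignored = rho[, 2],
    rho_inflamed = rho[, 3],
    assigned = vapply(res, `[[`, "", "assigned"),
    reason = vapply(res, `[[`, "", "reason")
  )
}

#' @describeIn classify_samples `predict()` method delegating to
#'   `classify_samples()`.
#' @param object A `spatial_classifier`.
#' @param ... Passed on to `classify_samples()`.
#' @export
predict.spatial_classifier <- function(object, expr, ...) {
  classify_samples(expr, object, ...)
}

#' Phenotype proportions among assigned samples
#'
#' Summarizes a [classify_samples()] result: counts and proportions per
#' phenotype over the assigned samples; unassigned samples are reported in
#' the `n_unassigned` attribute and excluded from the proportions.
#'
#' @param assignments Tibble from [classify_samples()].
#' @return Tibble `phenotype`, `n`, `prop`, with attribute `n_unassigned`.
#' @export
phenotype_proportions <- function(assignments) {
  check_columns(assignments, "assigned", "assignments")
  ok <- assignments$assigned %in% phenotype_levels()
  tab <- table(factor(assignments$assigned[ok], levels = phenotype_levels()))
  out <- tibble::tibble(phenotype = names(tab),
                        n = as.integer(tab),
                        prop = as.integer(tab) / max(sum(tab), 1L))
  attr(out, "n_unassigned") <- sum(!ok)
  out
}
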