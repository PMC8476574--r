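#' The three spatial immunophenotypes
#'
#' Fixed label set and order used throughout the package: `excluded`,
#' `ignored`, `inflamed`.
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' phenotype_levels()
phenotype_levels <- function() c("excluded", "ignored", "inflamed")

abort_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input("`", name, "` must be a single finite number")
  }
  if (x < min || (!allow_min && x == min) || x > max) {
    abort_input("`", name, "` must be in ", if (allow_min) "[" else "(",
                min, ", ", max, "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    abort_input("`", name, "` must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) {
    abort_input("`seed` is required; simulators never rely on global RNG state")
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) abort_input("`", name, "` must be a data frame")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_input("`", name, "` is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Expression tibble (gene_id + one column per sample) -> numeric matrix.
expr_matrix <- function(expr) {
  check_columns(expr, "gene_id", "expr")
  if (names(expr)[1] != "gene_id") {
    abort_input("`expr` must have `gene_id` as its first column")
  }
  if (anyDuplicated(expr$gene_id)) abort_input("duplicated gene ids in `expr`")
  if (ncol(expr) < 2L) abort_input("`expr` has no sample columns")
  if (anyDuplicated(names(expr))) abort_input("duplicated sample ids in `expr`")
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_input("expression values must be numeric")
  rownames(m) <- expr$gene_id
  m
}

# Align stained phenotype labels to the columns of an expression matrix.
aligned_labels <- function(m, annotations, require_all = TRUE) {
  check_columns(annotations, c("sample_id", "stained_phenotype"), "annotations")
  idx <- match(colnames(m), annotations$sample_id)
  if (require_all && anyNA(idx)) {
    abort_input("samples without annotation: ",
                paste(head(colnames(m)[is.na(idx)], 5), collapse = ", "))
  }
  lab <- annotations$stained_phenotype[idx]
  bad <- !is.na(lab) & !lab %in% phenotype_levels()
  if (any(bad)) {
    abort_input("unknown phenotype label(s): ", paste(unique(lab[bad]), collapse = ", "))
  }
  lab
}

# Coerce an outcome vector to logical "is positive".
as_binary <- function(x, positive = NULL, name = "outcome") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort_input("numeric `", name, "` must be 0/1")
    return(x == 1)
  }
  x <- as.character(x)
  if (is.null(positive)) {
    if (all(x %in% c("responder", "nonresponder"))) {
      positive <- "responder"
    } else {
      abort_input("`positive` must name the positive level of `", name, "`")
    }
  }
  if (!positive %in% x && !all(x %in% c(positive, setdiff(unique(x), positive)))) {
    abort_input("positive level not found in `", name, "`")
  }
  x == positive
}

`%||%` <- function(a, b) if (is.null(a)) b else a
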