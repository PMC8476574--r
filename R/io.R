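#' Read and write the package's text formats
#'
#' Plain-text dialects shared by all stages: expression matrices as TSV with
#' a `gene_id` first column and one column per sample; sample annotations as
#' TSV (`sample_id`, `stained_phenotype`, optionally `response`, `cohort`);
#' cell tables as CSV (`sample_id`, `stamp_id`, `region`, `compartment`,
#' `marker`, `x_um`, `y_um`); TCR repertoires as TSV (`clonotype_id`,
#' `cdr3_aa`, `count`, a subset of a MiXCR-style clonotype export); and the
#' trained classifier as TSV (gene id, signature phenotype, per-phenotype
#' centroid means and ranks).
#'
#' @param path File path.
#' @param expr,annotations,cells,repertoire,model Objects to write.
#' @return Readers return tibbles ([read_classifier()] a
#'   `spatial_classifier`); writers return their input invisibly.
#' @name spatialpheno-io
NULL

#' @rdname spatialpheno-io
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  expr_matrix(expr) # validate shape
  expr
}

#' @rdname spatialpheno-io
#' @export
write_expression <- function(expr, path) {
  if (inherits(expr, "expression_cohort")) expr <- expr$expression
  expr_matrix(expr)
  readr::write_tsv(expr, path)
  invisible(expr)
}

#' @rdname spatialpheno-io
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(ann, "sample_id", "annotations")
  ann
}

#' @rdname spatialpheno-io
#' @export
write_annotations <- function(annotations, path) {
  check_columns(annotations, "sample_id", "annotations")
  readr::write_tsv(annotations, path)
  invisible(annotations)
}

#' @rdname spatialpheno-io
#' @export
read_cell_table <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE)
  check_cells(cells)
  cells
}

#' @rdname spatialpheno-io
#' @export
write_cell_table <- function(cells, path) {
  check_cells(cells)
  readr::write_csv(cells, path)
  invisible(cells)
}

#' @rdname spatialpheno-io
#' @export
read_repertoire <- function(path) {
  rep_tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(rep_tbl, c("clonotype_id", "count"), "repertoire")
  rep_tbl
}

#' @rdname spatialpheno-io
#' @export
write_repertoire <- function(repertoire, path) {
  check_columns(repertoire, c("clonotype_id", "count"), "repertoire")
  readr::write_tsv(repertoire, path)
  invisible(repertoire)
}

#' @rdname spatialpheno-io
#' @export
write_classifier <- function(model, path) {
  if (!inherits(model, "spatial_classifier")) {
    abort_input("`model` must be a spatial_classifier")
  }
  readr::write_tsv(model$genes, path)
  invisible(model)
}

#' @rdname spatialpheno-io
#' @export
read_classifier <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "signature_phenotype",
            paste0("mean_", phenotype_levels()),
            paste0("rank_", phenotype_levels()))
  check_columns(genes, need, "classifier table")
  for (p in phenotype_levels()) {
    r <- genes[[paste0("rank_", p)]]
    if (!isTRUE(all.equal(r, rank(genes[[paste0("mean_", p)]],
                                  ties.method = "average")))) {
      abort_input("rank_", p, " is not the average-rank vector of mean_", p)
    }
  }
  structure(list(genes = genes, phenotypes = phenotype_levels()),
            class = "spatial_classifier")
}
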