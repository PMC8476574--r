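#' Imaging stamp geometry
#'
#' A stamp is a fixed rectangular field of view of 670 x 502 um
#' (0.33634 mm^2) in which cells are segmented and counted. Samples with
#' fewer than `min_stamps_per_region` stamps at either the border or the
#' center are flagged and excluded from phenotype assignment.
#'
#' @param width_um,height_um Stamp dimensions in micrometers.
#' @param min_stamps_per_region Minimum usable stamps per region (default 3).
#' @return A list with the dimensions, the minimum stamp rule and the derived
#'   `area_mm2`.
#' @export
#' @examples
#' stamp_geometry()$area_mm2
stamp_geometry <- function(width_um = 670, height_um = 502,
                           min_stamps_per_region = 3) {
  check_number(width_um, "width_um", min = 0, allow_min = FALSE)
  check_number(height_um, "height_um", min = 0, allow_min = FALSE)
  min_stamps_per_region <- check_count(min_stamps_per_region,
                                       "min_stamps_per_region", min = 1L)
  list(width_um = width_um, height_um = height_um,
       min_stamps_per_region = min_stamps_per_region,
       area_mm2 = width_um * height_um / 1e6)
}

#' Density thresholds of the digital phenotype rule
#'
#' @param high_border Border CD8 density (cells/mm^2) above which a sample is
#'   inflamed or excluded (default 200).
#' @param low_both Density below which both regions must fall for the ignored
#'   phenotype (default 150).
#' @param ratio_cut Border:center density ratio separating excluded (> cut)
#'   from inflamed (< cut) among high-border samples (default 10).
#' @return A named list of the three thresholds.
#' @export
phenotype_thresholds <- function(high_border = 200, low_both = 150,
                                 ratio_cut = 10) {
  check_number(high_border, "high_border", min = 0)
  check_number(low_both, "low_both", min = 0, max = high_border)
  check_number(ratio_cut, "ratio_cut", min = 1, allow_min = FALSE)
  list(high_border = high_border, low_both = low_both, ratio_cut = ratio_cut)
}

check_cells <- function(cells, geometry = NULL) {
  check_columns(cells, c("sample_id", "stamp_id", "region", "marker",
                         "x_um", "y_um"), "cells")
  bad_region <- setdiff(unique(cells$region), c("border", "center"))
  if (length(bad_region)) {
    abort_input("unknown region value(s): ", paste(bad_region, collapse = ", "))
  }
  if ("compartment" %in% names(cells)) {
    bad_comp <- setdiff(unique(cells$compartment), c("tumor", "stroma"))
    if (length(bad_comp)) {
      abort_input("unknown compartment value(s): ",
                  paste(bad_comp, collapse = ", "))
    }
  }
  invisible(cells)
}

#' Cell densities per marker, region and sample
#'
#' Pools all stamps of a region: density = total cell count / (number of
#' stamps x stamp area in mm^2). Stamp counts are inferred from the distinct
#' `stamp_id`s seen per sample and region unless `stamps` declares them
#' explicitly (needed when some stamps are empty). Samples with fewer than
#' `geometry$min_stamps_per_region` stamps in either region get
#' `qc = "insufficient_stamps"`; a region with zero stamps yields missing
#' densities.
#'
#' @param cells Cell table tibble (see [sim_cell_pattern()] for the dialect).
#' @param geometry A [stamp_geometry()].
#' @param by_compartment Also split densities by tumor/stroma compartment.
#' @param stamps Optional tibble `sample_id`, `region`, `n_stamps` declaring
#'   stamp counts; defaults to the `"stamps"` attribute that
#'   [sim_cell_pattern()] attaches, else to the observed stamp ids.
#' @param markers Optional marker set to report; defaults to the markers
#'   observed in `cells`.
#' @return Tibble with `sample_id`, `marker`, `region` (and `compartment`),
#'   `n_cells`, `n_stamps`, `density_per_mm2`, `qc`.
#' @export
#' @examples
#' cells <- sim_cell_pattern("excluded", seed = 1)
#' compute_densities(cells)
compute_densities <- function(cells, geometry = stamp_geometry(),
                              by_compartment = FALSE, stamps = NULL,
                              markers = NULL) {
  check_cells(cells)
  stamps <- stamps %||% attr(cells, "stamps")
  markers <- markers %||% sort(unique(cells$marker))
  samples <- unique(c(cells$sample_id, stamps$sample_id))
  if (length(samples) == 0L || length(markers) == 0L) {
    abort_input("no samples or markers to summarize; declare `markers` and ",
                "`stamps` for empty cell tables")
  }

  if (is.null(stamps)) {
    stamps <- dplyr::count(
      dplyr::distinct(cells, .data$sample_id, .data$region, .data$stamp_id),
      .data$sample_id, .data$region, name = "n_stamps")
  } else {
    check_columns(stamps, c("sample_id", "region", "n_stamps"), "stamps")
  }
  stamps <- tidyr::complete(stamps,
                            sample_id = samples,
                            region = c("border", "center"),
                            fill = list(n_stamps = 0L))

  keys <- c("sample_id", "region", "marker", if (by_compartment) "compartment")
  counts <- dplyr::count(cells, dplyr::across(dplyr::all_of(keys)),
                         name = "n_cells")
  grid <- list(sample_id = samples, region = c("border", "center"),
               marker = markers)
  if (by_compartment) grid$compartment <- c("tumor", "stroma")
  counts <- tidyr::complete(counts, !!!grid, fill = list(n_cells = 0L))

  out <- dplyr::left_join(counts, stamps, by = c("sample_id", "region"))
  out$density_per_mm2 <- ifelse(out$n_stamps > 0,
                                out$n_cells / (out$n_stamps * geometry$area_mm2),
                                NA_real_)
  qc <- dplyr::summarise(
    dplyr::group_by(stamps, .data$sample_id),
    qc = ifelse(min(.data$n_stamps) < geometry$min_stamps_per_region,
                "insufficient_stamps", "ok"),
    .groups = "drop")
  out <- dplyr::left_join(out, qc, by = "sample_id")
  out <- dplyr::arrange(out, .data$sample_id, .data$marker, .data$region)
  attr(out, "geometry") <- geometry
  out
}

#' Digital phenotype assignment from CD8 densities
#'
#' Applies the published density rule to border and center CD8+ T cell
#' densities (cells/mm^2): *inflamed* if border > 200 and border:center ratio
#' < 10; *excluded* if border > 200 and ratio > 10; *ignored* if both border
#' and center < 150. The ratio with a zero center density is taken as +Inf
#' (the limiting behavior of the rule), so a high border with an empty center
#' is excluded. Density combinations the published rule does not cover
#' (border in `[low_both, high_border]`; border < 150 with center >= 150;
#' ratio exactly at the cut) return `"unassigned"` with a machine-readable
#' reason rather than being coerced to a phenotype.
#'
#' @param border_cd8,center_cd8 Numeric densities in cells/mm^2 (vectorized).
#' @param thresholds A [phenotype_thresholds()].
#' @param detail If `TRUE`, return a tibble with the ratio and the reason for
#'   each decision instead of a bare label vector.
#' @return Character vector of labels (`excluded`, `ignored`, `inflamed`,
#'   `unassigned`), or a tibble when `detail = TRUE`.
#' @export
#' @examples
#' assign_phenotype_digital(c(250, 250, 100, 180), c(20, 100, 50, 5))
assign_phenotype_digital <- function(border_cd8, center_cd8,
                                     thresholds = phenotype_thresholds(),
                                     detail = FALSE) {
  if (length(border_cd8) != length(center_cd8)) {
    abort_input("`border_cd8` and `center_cd8` must have the same length")
  }
  if (any(border_cd8 < 0, na.rm = TRUE) || any(center_cd8 < 0, na.rm = TRUE)) {
    abort_input("densities must be >= 0")
  }
  ratio <- ifelse(center_cd8 == 0,
                  ifelse(border_cd8 > 0, Inf, NaN),
                  border_cd8 / center_cd8)
  n <- length(border_cd8)
  phenotype <- rep("unassigned", n)
  reason <- rep("threshold_gap", n)

  hb <- thresholds$high_border
  lb <- thresholds$low_both
  rc <- thresholds$ratio_cut

  inflamed <- !is.na(border_cd8) & !is.na(center_cd8) &
    border_cd8 > hb & ratio < rc
  excluded <- !is.na(border_cd8) & !is.na(center_cd8) &
    border_cd8 > hb & ratio > rc
  ignored <- !is.na(border_cd8) & !is.na(center_cd8) &
    border_cd8 < lb & center_cd8 < lb

  phenotype[inflamed] <- "inflamed"
  phenotype[excluded] <- "excluded"
  phenotype[ignored] <- "ignored"
  reason[inflamed | excluded | ignored] <- "ok"
  at_cut <- !is.na(ratio) & border_cd8 > hb & ratio == rc
  reason[at_cut] <- "ratio_at_cutoff"
  missing <- is.na(border_cd8) | is.na(center_cd8)
  phenotype[missing] <- "unassigned"
  reason[missing] <- "missing_density"

  if (!detail) return(phenotype)
  tibble::tibble(border_cd8 = border_cd8, center_cd8 = center_cd8,
                 ratio = ratio, phenotype = phenotype, reason = reason)
}

#' Manual-scoring phenotype assignment from raw CD8 counts
#'
#' Mirrors the manual scoring criteria on raw border/center counts:
#' *ignored* when hardly any CD8+ T cells are present in either region
#' (both counts below `hardly_any`, default 10); *excluded* when the border
#' has more than `ratio_cut` (default 10) times the center count; *inflamed*
#' otherwise (approximately equal frequencies). The "hardly any" cutoff is
#' not quantified in the original scoring protocol; 10 cells per region is
#' the configurable default here.
#'
#' @param border_count,center_count Non-negative cell counts (vectorized).
#' @param hardly_any Count below which a region is treated as empty.
#' @param ratio_cut Border:center ratio above which the sample is excluded.
#' @return Character vector of phenotype labels.
#' @export
#' @examples
#' assign_phenotype_manual(c(500, 5, 300), c(20, 2, 250))
assign_phenotype_manual <- function(border_count, center_count,
                                    hardly_any = 10, ratio_cut = 10) {
  if (any(border_count < 0, na.rm = TRUE) || any(center_count < 0, na.rm = TRUE)) {
    abort_input("counts must be >= 0")
  }
  ratio <- ifelse(center_count == 0,
                  ifelse(border_count > 0, Inf, NaN),
                  border_count / center_count)
  out <- rep("inflamed", length(border_count))
  out[!is.na(ratio) & ratio > ratio_cut] <- "excluded"
  out[border_count < hardly_any & center_count < hardly_any] <- "ignored"
  out[is.na(border_count) | is.na(center_count)] <- "unassigned"
  out
}

#' CD8 densities and digital phenotype per sample
#'
#' End-to-end spatial phenotyping of a cell table: computes pooled CD8
#' densities per region (tumor and stroma combined, matching the unqualified
#' density rule; a per-stamp-median variant is available via
#' `method = "stamp_median"`) and applies [assign_phenotype_digital()].
#' Samples failing the minimum-stamp rule are reported `unassigned` with
#' reason `insufficient_stamps`.
#'
#' @inheritParams compute_densities
#' @param thresholds A [phenotype_thresholds()].
#' @param marker Marker whose density drives the rule (default `"CD8"`).
#' @param method `"pooled"` (total count over total area; default) or
#'   `"stamp_median"` (median of per-stamp densities per region).
#' @return Tibble with `sample_id`, `border_cd8_per_mm2`, `center_cd8_per_mm2`,
#'   `n_stamps_border`, `n_stamps_center`, `phenotype`, `reason`.
#' @export
#' @examples
#' cells <- sim_cell_pattern("excluded", seed = 11)
#' cd8_phenotypes(cells)
cd8_phenotypes <- function(cells, geometry = stamp_geometry(),
                           thresholds = phenotype_thresholds(),
                           marker = "CD8", stamps = NULL,
                           method = c("pooled", "stamp_median")) {
  method <- match.arg(method)
  check_cells(cells)
  stamps <- stamps %||% attr(cells, "stamps")

  if (method == "pooled") {
    dens <- compute_densities(cells, geometry, stamps = stamps,
                              markers = marker)
    dens <- dens[dens$marker == marker, ]
    wide <- tidyr::pivot_wider(
      dens, id_cols = c("sample_id", "qc"),
      names_from = "region",
      values_from = c("density_per_mm2", "n_stamps"))
  } else {
    cd8 <- cells[cells$marker == marker, ]
    per_stamp <- dplyr::count(cd8, .data$sample_id, .data$region,
                              .data$stamp_id, name = "n_cells")
    if (is.null(stamps)) {
      stamps <- dplyr::count(
        dplyr::distinct(cells, .data$sample_id, .data$region, .data$stamp_id),
        .data$sample_id, .data$region, name = "n_stamps")
    }
    declared <- dplyr::distinct(cells, .data$sample_id, .data$region,
                                .data$stamp_id)
    per_stamp <- dplyr::left_join(declared, per_stamp,
                                  by = c("sample_id", "region", "stamp_id"))
    per_stamp$n_cells[is.na(per_stamp$n_cells)] <- 0L
    med <- dplyr::summarise(
      dplyr::group_by(per_stamp, .data$sample_id, .data$region),
      density_per_mm2 = stats::median(.data$n_cells) / geometry$area_mm2,
      n_stamps = dplyr::n(), .groups = "drop")
    med <- tidyr::complete(med,
                           sample_id = unique(cells$sample_id),
                           region = c("border", "center"),
                           fill = list(n_stamps = 0L))
    med <- dplyr::mutate(
      dplyr::group_by(med, .data$sample_id),
      qc = ifelse(min(.data$n_stamps) < geometry$min_stamps_per_region,
                  "insufficient_stamps", "ok"))
    wide <- tidyr::pivot_wider(dplyr::ungroup(med),
                               id_cols = c("sample_id", "qc"),
                               names_from = "region",
                               values_from = c("density_per_mm2", "n_stamps"))
  }

  res <- assign_phenotype_digital(wide$density_per_mm2_border,
                                  wide$density_per_mm2_center,
                                  thresholds, detail = TRUE)
  out <- tibble::tibble(
    sample_id = wide$sample_id,
    border_cd8_per_mm2 = wide$density_per_mm2_border,
    center_cd8_per_mm2 = wide$density_per_mm2_center,
    n_stamps_border = wide$n_stamps_border,
    n_stamps_center = wide$n_stamps_center,
    phenotype = res$phenotype,
    reason = res$reason
  )
  flagged <- wide$qc == "insufficient_stamps"
  out$phenotype[flagged] <- "unassigned"
  out$reason[flagged] <- "insufficient_stamps"
  out
}

# Squared distances between two coordinate sets (rows of a, rows of b).
dist2 <- function(ax, ay, bx, by) {
  outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
}

#' Neighbor counts within a radius of reference cells
#'
#' For every cell of `reference_marker`, counts the cells of each marker
#' (including other cells of the reference marker; the reference cell itself
#' is excluded) within Euclidean distance `radius_um`, computed within the
#' same stamp only -- stamps are disjoint fields of view. The radius test is a
#' closed ball: a cell exactly at the radius is counted.
#'
#' @param cells Cell table tibble.
#' @param reference_marker Marker of the reference cells (e.g. `"CD8"`).
#' @param radius_um Radius in micrometers (default 10).
#' @return Tibble with one row per reference cell x marker: `sample_id`,
#'   `stamp_id`, `ref_cell` (row index in `cells`), `marker`, `n_neighbors`.
#'   Empty (with a warning) when the reference marker is absent.
#' @export
#' @examples
#' cells <- sim_cell_pattern("inflamed", seed = 5)
#' nb <- count_neighbors(cells, "CD8", radius_um = 10)
#' mean(nb$n_neighbors)
count_neighbors <- function(cells, reference_marker, radius_um = 10) {
  check_cells(cells)
  check_number(radius_um, "radius_um", min = 0, allow_min = FALSE)
  empty <- tibble::tibble(sample_id = character(), stamp_id = character(),
                          ref_cell = integer(), marker = character(),
                          n_neighbors = integer())
  if (!reference_marker %in% cells$marker) {
    warning("reference marker '", reference_marker, "' absent from `cells`")
    return(empty)
  }
  markers <- sort(unique(cells$marker))
  cells$.cell <- seq_len(nrow(cells))
  r2 <- radius_um^2

  parts <- split(cells, list(cells$sample_id, cells$stamp_id), drop = TRUE)
  res <- purrr::map(parts, function(st) {
    ref <- st[st$marker == reference_marker, ]
    if (nrow(ref) == 0L) return(NULL)
    d2 <- dist2(ref$x_um, ref$y_um, st$x_um, st$y_um)
    within <- d2 <= r2
    within[cbind(seq_len(nrow(ref)), match(ref$.cell, st$.cell))] <- FALSE
    counts <- vapply(markers, function(m) {
      cols <- st$marker == m
      as.integer(rowSums(within[, cols, drop = FALSE]))
    }, integer(nrow(ref)))
    counts <- matrix(counts, nrow = nrow(ref),
                     dimnames = list(NULL, markers))
    tibble::tibble(
      sample_id = rep(ref$sample_id, length(markers)),
      stamp_id = rep(ref$stamp_id, length(markers)),
      ref_cell = rep(ref$.cell, length(markers)),
      marker = rep(markers, each = nrow(ref)),
      n_neighbors = as.integer(counts)
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$ref_cell, .data$marker)
}

#' Per-cell nearest-neighbor distances between two markers
#'
#' For each cell of `reference_marker`, the Euclidean distance (um) to its
#' nearest `target_marker` cell within the same stamp. When reference and
#' target marker coincide, the nearest *other* cell of that marker is used.
#' Stamps without any target cell contribute no reference cells.
#'
#' @inheritParams count_neighbors
#' @param target_marker Marker of the target cells.
#' @return Tibble `sample_id`, `stamp_id`, `ref_cell`, `nn_dist_um`.
#' @export
nearest_distances <- function(cells, reference_marker, target_marker) {
  check_cells(cells)
  cells$.cell <- seq_len(nrow(cells))
  parts <- split(cells, list(cells$sample_id, cells$stamp_id), drop = TRUE)
  res <- purrr::map(parts, function(st) {
    ref <- st[st$marker == reference_marker, ]
    tgt <- st[st$marker == target_marker, ]
    if (nrow(ref) == 0L || nrow(tgt) == 0L) return(NULL)
    d2 <- dist2(ref$x_um, ref$y_um, tgt$x_um, tgt$y_um)
    self <- outer(ref$.cell, tgt$.cell, "==")
    d2[self] <- Inf
    nn <- apply(d2, 1L, min)
    keep <- is.finite(nn)
    if (!any(keep)) return(NULL)
    tibble::tibble(sample_id = ref$sample_id[keep],
                   stamp_id = ref$stamp_id[keep],
                   ref_cell = ref$.cell[keep],
                   nn_dist_um = sqrt(nn[keep]))
  })
  dplyr::bind_rows(res)
}

#' Mean nearest-neighbor distance between two markers
#'
#' Mean of [nearest_distances()] over all reference cells in the table
#' (pool across stamps and samples; group the cell table beforehand for
#' per-sample summaries).
#'
#' @inheritParams nearest_distances
#' @return A single distance in micrometers; `NA` with a warning when the
#'   target marker is absent everywhere.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   sample_id = "s", stamp_id = "st", region = "border",
#'   marker = c("CD8", "CK", "CK"),
#'   x_um = c(0, 3, 6), y_um = c(0, 4, 8))
#' mean_nearest_distance(cells, "CD8", "CK") # 3-4-5 triangle -> 5
mean_nearest_distance <- function(cells, reference_marker, target_marker) {
  nn <- nearest_distances(cells, reference_marker, target_marker)
  if (nrow(nn) == 0L) {
    warning("no reference-target pairs for markers '", reference_marker,
            "' vs '", target_marker, "'")
    return(NA_real_)
  }
  mean(nn$nn_dist_um)
}
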