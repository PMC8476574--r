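# Small in-code fixtures shared across test files.

tiny_cohort <- function(seed = 1, n = 10, markers = 5, noise = 50,
                        effect = 2, sd = 1) {
  sim_expression_cohort(n_per_phenotype = n, n_marker_genes = markers,
                        n_noise_genes = noise, effect_size = effect,
                        noise_sd = sd, seed = seed)
}

# Hand-built cell table: coordinates and markers fully controlled.
cells_at <- function(x, y, marker, stamp_id = "B01", region = "border",
                     sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, stamp_id = stamp_id, region = region,
                 compartment = "tumor", marker = marker, x_um = x, y_um = y)
}

# Independent brute-force oracles -------------------------------------------

brute_force_neighbors <- function(cells, reference_marker, radius_um) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    if (cells$marker[i] != reference_marker) next
    for (m in sort(unique(cells$marker))) {
      cnt <- 0L
      for (j in seq_len(nrow(cells))) {
        if (j == i || cells$marker[j] != m) next
        if (cells$sample_id[j] != cells$sample_id[i] ||
            cells$stamp_id[j] != cells$stamp_id[i]) next
        d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
        if (d <= radius_um) cnt <- cnt + 1L
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(ref_cell = i, marker = m, n_neighbors = cnt)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), ref_cell, marker)
}

brute_force_nearest <- function(cells, reference_marker, target_marker) {
  res <- c()
  for (i in seq_len(nrow(cells))) {
    if (cells$marker[i] != reference_marker) next
    best <- Inf
    for (j in seq_len(nrow(cells))) {
      if (j == i || cells$marker[j] != target_marker) next
      if (cells$sample_id[j] != cells$sample_id[i] ||
          cells$stamp_id[j] != cells$stamp_id[i]) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                (cells$y_um[i] - cells$y_um[j])^2)
      best <- min(best, d)
    }
    if (is.finite(best)) res <- c(res, best)
  }
  res
}

brute_force_auc <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
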