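# In-code fixtures shared across the suite.

channels <- plexquant::plex_channels()

# One well-behaved PSM row; override any field via ...
make_psm <- function(..., intensities = rep(1000, 8)) {
  row <- tibble::tibble(
    peptide_sequence = "ELVISLIVESK",
    modifications = "",
    protein_accession = "P001",
    is_unique = TRUE,
    charge = 2L,
    mascot_score = 50,
    sequest_xcorr = 3,
    sequest_dcn = 0.3,
    percolator_q = 0.001,
    rank = 1L,
    missed_cleavages = 0L,
    replicate_id = 1L
  )
  for (ch in seq_along(channels)) row[[channels[ch]]] <- intensities[ch]
  override <- list(...)
  for (nm in names(override)) row[[nm]] <- override[[nm]]
  row[, c(setdiff(names(row), channels), channels)]
}

# A mean-centered intensity table built from explicit channel rows.
# rows: list of named lists with feature metadata and a `values` numeric(8)
make_centered_matrix <- function(rows) {
  df <- purrr::map_dfr(rows, function(r) {
    out <- tibble::tibble(
      feature_id = r$feature_id %||%
        plexquant::feature_key(r$peptide_sequence %||% "PEPTIDEK",
                               r$modifications %||% ""),
      peptide_sequence = r$peptide_sequence %||% "PEPTIDEK",
      modifications = r$modifications %||% "",
      protein_accession = r$protein_accession %||% "P001",
      is_unique = r$is_unique %||% TRUE,
      replicate_id = r$replicate_id %||% 1L
    )
    for (ch in seq_along(channels)) out[[channels[ch]]] <- r$values[ch]
    out
  })
  plexquant:::set_scale_state(df, "mean_centered")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small long-format Ct table: ct_matrix is targets x samples, sample
# names GENOTYPE_REP
make_ct <- function(ct_matrix) {
  tibble::as_tibble(ct_matrix, rownames = "target") |>
    tidyr::pivot_longer(-target, names_to = "sample", values_to = "ct") |>
    dplyr::mutate(genotype = sub("_.*", "", sample),
                  replicate = as.integer(sub(".*_", "", sample)))
}

# ratio table from explicit per-replicate ratios (list of numeric(n))
make_ratios <- function(ratio_list, region = "neocortex",
                        feature_ids = paste0("f", seq_along(ratio_list))) {
  n_rep <- length(ratio_list[[1]])
  df <- tibble::tibble(feature_id = feature_ids, region = region)
  for (r in seq_len(n_rep)) {
    df[[paste0("ratio_rep", r)]] <-
      vapply(ratio_list, function(x) x[r], numeric(1))
  }
  plexquant::summarise_ratio_rows(df)
}
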