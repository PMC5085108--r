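#' Run the full quantification pipeline
#'
#' End-to-end convenience wrapper over the module functions:
#' \enumerate{
#'   \item [filter_psms()]: search-engine confidence filtering;
#'   \item [psm_to_log2()], [median_normalize()], [center_features()]:
#'     log2 transform, per-channel median normalization, per-replicate
#'     feature mean-centering;
#'   \item [rollup_ptm()] / [rollup_protein()]: merge modified peptides
#'     and proteins;
#'   \item [compute_ratios()]: per-region AD/WT replicate ratios;
#'   \item [normalize_ptm_ratios()]: PTM ratios divided by protein
#'     ratios (including single-peptide proteins);
#'   \item [check_sequon()]: N-glycosylation motif validation of
#'     deglyco features;
#'   \item [call_deregulation()]: presence / relative-SD / fold-change
#'     calling;
#'   \item [run_pca()]: sample-quality PCA on the centered peptide
#'     matrix.
#' }
#'
#' @param psms PSM tibble covering all replicates.
#' @param db Protein database (named character vector) for sequon
#'   validation; `NULL` treats all sequons as unverifiable (deglyco
#'   features then fail the sequon flag).
#' @param design Channel design.
#' @param thresholds A [default_thresholds()] object.
#' @param n_replicates Number of biological replicates; default the
#'   largest replicate id present.
#' @return A list with elements `peptides` (centered intensity table),
#'   `protein_calls`, `ptm_calls` (called ratio tibbles), `ptm_features`
#'   (feature annotation incl. sites), `pca` (a `plex_pca`), and
#'   `thresholds`.
#' @examples
#' sim <- simulate_study(simulation_params(n_proteins = 20, seed = 3))
#' res <- run_quant_pipeline(sim$psms, sim$proteome$db)
#' table(res$ptm_calls$direction)
#' @export
run_quant_pipeline <- function(psms, db = NULL,
                               design = default_channel_design(),
                               thresholds = default_thresholds(),
                               n_replicates = max(psms$replicate_id)) {
  kept <- filter_psms(psms, thresholds)
  centered <- kept |>
    psm_to_log2() |>
    median_normalize() |>
    center_features()
  ptm_mat <- rollup_ptm(centered)
  prot <- rollup_protein(centered)
  prot_ratios <- compute_ratios(prot$proteins, design,
                                n_replicates = n_replicates)
  prot_all <- dplyr::bind_rows(prot$proteins, prot$single_peptide)
  attr(prot_all, "scale_state") <- "mean_centered"
  prot_all_ratios <- compute_ratios(prot_all, design,
                                    n_replicates = n_replicates)
  prot_all_ratios$feature_id <- prot_all_ratios$protein_accession
  ptm_ratios <- compute_ratios(ptm_mat, design,
                               n_replicates = n_replicates)
  # one-hit-wonders are allowed for PTM features: the two-peptide
  # identification rule applies to proteins only
  ptm_ratios$min_peptides <- NULL
  ptm_ratios <- normalize_ptm_ratios(ptm_ratios, prot_all_ratios)
  feats <- ptm_features(ptm_mat, db)
  sequon_ok <- rep(TRUE, nrow(feats))
  glyco <- which(feats$feature_kind == "deglyco")
  sequon_ok[glyco] <- vapply(glyco, function(i) {
    pos <- feats$site_positions[[i]]
    if (is.null(db) || length(pos) == 0) return(FALSE)
    all(check_sequon(db, feats$protein_accession[i], pos))
  }, logical(1))
  sequon <- tibble::tibble(feature_id = feats$feature_id,
                           feature_kind = feats$feature_kind,
                           sequon_ok = sequon_ok)
  ptm_ratios <- dplyr::left_join(ptm_ratios, sequon, by = "feature_id")
  protein_calls <- call_deregulation(prot_ratios, thresholds, n_replicates)
  protein_calls$feature_id <- protein_calls$protein_accession
  ptm_calls <- call_deregulation(ptm_ratios, thresholds, n_replicates)
  pca <- run_pca(centered, design)
  list(peptides = centered,
       protein_calls = protein_calls,
       ptm_calls = ptm_calls,
       ptm_features = feats,
       pca = pca,
       thresholds = thresholds)
}

#' Write deregulation result tables
#'
#' Emits `proteins_deregulated.tsv` and `ptm_deregulated.tsv` with the
#' per-replicate ratios, summaries, flags and call direction.
#'
#' @param result Output of [run_quant_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_deregulation_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drop_lists <- function(df) df[, !vapply(df, is.list, logical(1))]
  readr::write_tsv(drop_lists(result$protein_calls),
                   file.path(dir, "proteins_deregulated.tsv"),
                   progress = FALSE)
  readr::write_tsv(drop_lists(result$ptm_calls),
                   file.path(dir, "ptm_deregulated.tsv"), progress = FALSE)
  invisible(dir)
}
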