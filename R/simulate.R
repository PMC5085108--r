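#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline is built for: an 8-plex design of
#' 4 brain regions x {WT, AD} with 3 biological replicates, a
#' protein -> peptide -> PTM hierarchy, log-normal reporter noise
#' calibrated so null AD/WT replicate ratios have an 8.4\% coefficient
#' of variation, and spiked deregulation of |log2 fold change| = 1 at
#' both protein and PTM level.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Integer range (min, max) of tryptic
#'   peptides per protein.
#' @param fraction_ptm_peptides Probability that a peptide (beyond the
#'   two guaranteed unmodified ones) carries a PTM.
#' @param fraction_deregulated_proteins Per-region probability that a
#'   protein is deregulated.
#' @param fraction_deregulated_ptm Per-region probability that a PTM
#'   feature carries a PTM-level effect (on top of any protein effect).
#' @param n_shared_ptm Number of PTM features deregulated in all four
#'   regions (same direction), exercising cross-region overlap logic.
#' @param effect_log2 Absolute spiked log2 AD/WT effect.
#' @param technical_cv Coefficient of variation of null per-replicate
#'   AD/WT ratios (linear scale).
#' @param channel_bias_range Uniform range of per-(channel, replicate)
#'   loading offsets on the log2 scale.
#' @param missing_rate Probability that a feature's two channels of one
#'   region are missing in a replicate (channel-block-wise missingness).
#' @param fraction_low_quality Share of extra PSMs that violate exactly
#'   one confidence criterion (filter fodder).
#' @param fraction_nonunique Share of unmodified peptides flagged as
#'   mapping to more than one protein entry.
#' @param region_effect_sd SD of per-(protein, region) biological
#'   offsets shared by both genotypes (drives region structure in PCA;
#'   cancels in AD/WT ratios).
#' @param n_replicates Number of biological replicates.
#' @param base_log2_mean,base_log2_sd Log2 abundance distribution of
#'   peptides.
#' @param n_targets Number of qPCR targets.
#' @param fraction_deregulated_targets Share of deregulated qPCR
#'   targets.
#' @param ct_fold_change Linear fold change spiked into deregulated
#'   qPCR targets.
#' @param seed Integer seed fixing the full output.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_proteins = 150,
                              peptides_per_protein = c(4L, 8L),
                              fraction_ptm_peptides = 0.3,
                              fraction_deregulated_proteins = 0.05,
                              fraction_deregulated_ptm = 0.05,
                              n_shared_ptm = 5L,
                              effect_log2 = 1,
                              technical_cv = 0.084,
                              channel_bias_range = c(-0.3, 0.3),
                              missing_rate = 0.05,
                              fraction_low_quality = 0.1,
                              fraction_nonunique = 0.02,
                              region_effect_sd = 0.5,
                              n_replicates = 3L,
                              base_log2_mean = 20,
                              base_log2_sd = 1.5,
                              n_targets = 84L,
                              fraction_deregulated_targets = 0.1,
                              ct_fold_change = 2,
                              seed = 42L) {
  stopifnot(
    technical_cv > 0, effect_log2 >= 0, n_replicates >= 2,
    all(c(fraction_ptm_peptides, fraction_deregulated_proteins,
          fraction_deregulated_ptm, missing_rate, fraction_low_quality,
          fraction_nonunique, fraction_deregulated_targets) >= 0),
    all(c(fraction_ptm_peptides, fraction_deregulated_proteins,
          fraction_deregulated_ptm, missing_rate, fraction_low_quality,
          fraction_nonunique, fraction_deregulated_targets) <= 1)
  )
  structure(as.list(environment()), class = "simulation_params")
}

# log2-scale sd of a null AD/WT ratio with linear CV = cv; each of the
# two channels gets sd/sqrt(2) so the ratio CV equals cv
ratio_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

sample_direction <- function(n, fraction) {
  sample(c("up", "down", "none"), n, replace = TRUE,
         prob = c(fraction / 2, fraction / 2, 1 - fraction))
}

random_tryptic_peptide <- function(len, kind = c("plain", "phospho", "deglyco")) {
  kind <- match.arg(kind)
  interior <- setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], character())
  repeat {
    body <- sample(interior, len - 1, replace = TRUE)
    if (body[1] == "P") next
    mod <- ""
    if (kind == "phospho") {
      pos <- sample(2:(len - 2), 1)
      body[pos] <- sample(c("S", "T", "Y"), 1)
      mod <- paste0(pos, ":phospho")
    } else if (kind == "deglyco") {
      pos <- sample(2:(len - 4), 1)
      body[pos] <- "N"
      body[pos + 1] <- sample(setdiff(interior, c("P", "N")), 1)
      body[pos + 2] <- sample(c("S", "T", "C"), 1)
      mod <- paste0(pos, ":deamidation")
    }
    pep <- paste0(paste(body, collapse = ""), sample(c("K", "R"), 1))
    return(list(sequence = pep, modifications = mod))
  }
}

#' Generate a synthetic proteome
#'
#' Builds random protein sequences as concatenations of unique tryptic
#' peptides (each ending in K/R, interior free of K/R, not starting
#' with P). Each protein carries at least two unmodified peptides;
#' further peptides may be designated phospho (an S/T/Y site) or
#' formerly glycosylated (a planted N-X-S/T/C sequon, X != P, with a
#' deamidation at the Asn). Deterministic under `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `db` (named character vector, the FASTA content)
#'   and `peptides` (tibble: `protein_accession`, `peptide_sequence`,
#'   `modifications`, `start` protein coordinate, `is_unique`,
#'   `feature_id`, `is_ptm`, `ptm_type`).
#' @export
simulate_proteome <- function(params = simulation_params()) {
  set.seed(params$seed)
  p <- params
  seen <- new.env(parent = emptyenv())
  rows <- vector("list", p$n_proteins)
  for (i in seq_len(p$n_proteins)) {
    acc <- sprintf("SIM%04d", i)
    k <- sample(seq(p$peptides_per_protein[1], p$peptides_per_protein[2]), 1)
    kinds <- c("plain", "plain",
               ifelse(stats::runif(max(k - 2, 0)) < p$fraction_ptm_peptides,
                      sample(c("phospho", "deglyco"), max(k - 2, 0),
                             replace = TRUE), "plain"))
    peps <- vector("list", k)
    for (j in seq_len(k)) {
      repeat {
        cand <- random_tryptic_peptide(sample(9:16, 1), kinds[j])
        if (is.null(seen[[cand$sequence]])) {
          seen[[cand$sequence]] <- TRUE
          peps[[j]] <- cand
          break
        }
      }
    }
    seqs <- vapply(peps, `[[`, "", "sequence")
    start <- cumsum(c(1, utils::head(nchar(seqs), -1)))
    rows[[i]] <- tibble::tibble(
      protein_accession = acc,
      peptide_sequence = seqs,
      modifications = vapply(peps, `[[`, "", "modifications"),
      start = start,
      is_ptm = kinds != "plain",
      ptm_type = ifelse(kinds == "plain", NA_character_, kinds)
    )
  }
  peptides <- dplyr::bind_rows(rows)
  peptides$is_unique <- TRUE
  # flag a share of unmodified peptides (never the first two of a
  # protein) as ambiguous
  cand <- peptides |>
    dplyr::mutate(row = dplyr::row_number()) |>
    dplyr::group_by(.data$protein_accession) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$is_ptm, .data$idx > 2) |>
    dplyr::pull(.data$row)
  if (length(cand)) {
    flip <- cand[stats::runif(length(cand)) < p$fraction_nonunique]
    peptides$is_unique[flip] <- FALSE
  }
  peptides$feature_id <- feature_key(peptides$peptide_sequence,
                                     peptides$modifications)
  db <- peptides |>
    dplyr::group_by(.data$protein_accession) |>
    dplyr::summarise(sequence = paste(.data$peptide_sequence, collapse = ""),
                     .groups = "drop")
  list(db = stats::setNames(db$sequence, db$protein_accession),
       peptides = peptides)
}

simulate_truth <- function(params, proteome) {
  p <- params
  regions <- plex_regions()
  prot_truth <- tidyr::expand_grid(
    feature_id = unique(proteome$peptides$protein_accession),
    region = regions
  ) |>
    dplyr::mutate(
      level = "protein",
      direction = sample_direction(dplyr::n(),
                                   p$fraction_deregulated_proteins)
    )
  ptm_feats <- proteome$peptides$feature_id[proteome$peptides$is_ptm]
  ptm_truth <- tidyr::expand_grid(feature_id = ptm_feats,
                                  region = regions) |>
    dplyr::mutate(
      level = "ptm",
      direction = sample_direction(dplyr::n(), p$fraction_deregulated_ptm)
    )
  n_shared <- min(p$n_shared_ptm, length(ptm_feats))
  if (n_shared > 0) {
    shared <- sample(ptm_feats, n_shared)
    shared_dir <- stats::setNames(sample(c("up", "down"), n_shared,
                                         replace = TRUE), shared)
    hit <- ptm_truth$feature_id %in% shared
    ptm_truth$direction[hit] <- shared_dir[ptm_truth$feature_id[hit]]
  }
  dplyr::bind_rows(prot_truth, ptm_truth)
}

effect_sign <- function(direction) {
  ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
}

#' Generate synthetic PSM tables with ground truth
#'
#' Simulates, for every peptide feature and replicate, one well-scored
#' PSM with eight raw reporter intensities:
#' `log2 I = peptide abundance + region offset + channel loading bias
#' + genotype effect + noise`. Protein-level effects apply to all of a
#' protein's peptides in the affected region's AD channel; PTM-level
#' effects apply only to the modified peptide, on top of any protein
#' effect, so protein-level change is absorbed by PTM-over-protein
#' normalization while PTM-level change survives it. Noise is log2
#' normal with sd `sqrt(ln(1 + cv^2))/ln 2 / sqrt(2)` per channel so
#' that a null AD/WT replicate ratio has linear CV = `technical_cv`.
#' A configurable share of extra PSMs each violates exactly one
#' confidence criterion. Missingness is applied per (feature,
#' replicate, region) to both of the region's channels. Deterministic
#' under `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @param proteome Output of [simulate_proteome()].
#' @return A list: `psms` (one PSM tibble covering all replicates),
#'   `truth` (tibble `feature_id`, `region`, `level`, `direction`).
#' @export
simulate_psm_tables <- function(params = simulation_params(),
                                proteome = simulate_proteome(params)) {
  p <- params
  set.seed(p$seed + 1L)
  truth <- simulate_truth(p, proteome)
  design <- default_channel_design()
  chan <- plex_channels()
  peps <- proteome$peptides
  n_feat <- nrow(peps)
  sigma_chan <- ratio_log2_sd(p$technical_cv) / sqrt(2)
  base <- stats::rnorm(n_feat, p$base_log2_mean, p$base_log2_sd)
  region_off <- matrix(stats::rnorm(p$n_proteins * 4, 0, p$region_effect_sd),
                       nrow = p$n_proteins,
                       dimnames = list(unique(peps$protein_accession),
                                       plex_regions()))
  prot_truth <- truth[truth$level == "protein", ]
  prot_eff <- matrix(0, p$n_proteins, 4,
                     dimnames = dimnames(region_off))
  prot_eff[cbind(prot_truth$feature_id, prot_truth$region)] <-
    effect_sign(prot_truth$direction) * p$effect_log2
  ptm_truth <- truth[truth$level == "ptm", ]
  ptm_eff <- matrix(0, length(unique(ptm_truth$feature_id)), 4,
                    dimnames = list(unique(ptm_truth$feature_id),
                                    plex_regions()))
  if (nrow(ptm_truth)) {
    ptm_eff[cbind(ptm_truth$feature_id, ptm_truth$region)] <-
      effect_sign(ptm_truth$direction) * p$effect_log2
  }
  good_scores <- function(n) {
    charge <- sample(2:4, n, replace = TRUE)
    bound <- c(`2` = 2, `3` = 2.25, `4` = 2.5)[as.character(charge)]
    tibble::tibble(
      charge = charge,
      mascot_score = stats::runif(n, 25, 120),
      sequest_xcorr = unname(bound) + stats::runif(n, 0.05, 2),
      sequest_dcn = stats::runif(n, 0.15, 0.6),
      percolator_q = stats::runif(n, 0, 0.009),
      rank = 1L,
      missed_cleavages = sample(0:1, n, replace = TRUE, prob = c(0.85, 0.15))
    )
  }
  reps <- vector("list", p$n_replicates)
  for (r in seq_len(p$n_replicates)) {
    bias <- stats::setNames(stats::runif(8, p$channel_bias_range[1],
                                         p$channel_bias_range[2]), chan)
    intens <- matrix(NA_real_, n_feat, 8, dimnames = list(NULL, chan))
    for (ci in seq_along(chan)) {
      rg <- design$region[ci]
      gt <- design$genotype[ci]
      eff <- if (gt == "AD") {
        e <- prot_eff[peps$protein_accession, rg]
        is_ptm_row <- peps$is_ptm
        e[is_ptm_row] <- e[is_ptm_row] +
          ptm_eff[peps$feature_id[is_ptm_row], rg]
        e
      } else 0
      log2i <- base + region_off[peps$protein_accession, rg] +
        bias[ci] + eff + stats::rnorm(n_feat, 0, sigma_chan)
      intens[, ci] <- 2^log2i
    }
    for (rg in plex_regions()) {
      block <- design$channel[design$region == rg]
      gone <- stats::runif(n_feat) < p$missing_rate
      intens[gone, block] <- NA_real_
    }
    good <- dplyr::bind_cols(
      tibble::tibble(
        peptide_sequence = peps$peptide_sequence,
        modifications = peps$modifications,
        protein_accession = peps$protein_accession,
        is_unique = peps$is_unique
      ),
      good_scores(n_feat),
      tibble::as_tibble(intens)
    )
    good$replicate_id <- r
    n_bad <- round(p$fraction_low_quality * n_feat)
    if (n_bad > 0) {
      idx <- sample(n_feat, n_bad)
      bad <- good[idx, ]
      defect <- sample(c("mascot", "q", "dcn", "xcorr", "rank", "mc"),
                       n_bad, replace = TRUE)
      bad$mascot_score[defect == "mascot"] <-
        stats::runif(sum(defect == "mascot"), 0, 21.9)
      bad$percolator_q[defect == "q"] <-
        stats::runif(sum(defect == "q"), 0.011, 0.2)
      bad$sequest_dcn[defect == "dcn"] <-
        stats::runif(sum(defect == "dcn"), 0, 0.099)
      bad$sequest_xcorr[defect == "xcorr"] <-
        stats::runif(sum(defect == "xcorr"), 0, 1.4)
      bad$rank[defect == "rank"] <- 2L
      bad$missed_cleavages[defect == "mc"] <- 2L
      good <- dplyr::bind_rows(good, bad)
    }
    reps[[r]] <- good
  }
  psms <- dplyr::bind_rows(reps)[, c(psm_meta_cols(), chan)]
  validate_psm_table(psms)
  list(psms = psms, truth = truth)
}

#' Generate a synthetic qPCR Ct table with ground truth
#'
#' `Ct = target baseline + sample plate offset - expression shift +
#' noise`; deregulated targets shift the AD group mean by
#' `-log2(fold change)` (up) or `+log2(fold change)` (down). The
#' per-sample plate offset is removed by median-of-targets
#' normalization. Noise sd in Ct units equals the log2-scale sd
#' implied by `technical_cv`. Deterministic under `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A list: `ct` (long Ct tibble) and `truth` (tibble `target`,
#'   `direction`).
#' @export
simulate_ct_table <- function(params = simulation_params()) {
  p <- params
  set.seed(p$seed + 2L)
  targets <- sprintf("target_%03d", seq_len(p$n_targets))
  direction <- sample_direction(p$n_targets, p$fraction_deregulated_targets)
  samples <- tidyr::expand_grid(genotype = c("WT", "AD"),
                                replicate = seq_len(p$n_replicates)) |>
    dplyr::mutate(sample = paste0(.data$genotype, "_", .data$replicate),
                  offset = stats::runif(dplyr::n(), -1, 1))
  baseline <- stats::runif(p$n_targets, 22, 30)
  shift <- effect_sign(direction) * log2(p$ct_fold_change)
  noise_sd <- ratio_log2_sd(p$technical_cv)
  ct <- tidyr::expand_grid(ti = seq_len(p$n_targets),
                           si = seq_len(nrow(samples))) |>
    dplyr::mutate(
      target = targets[.data$ti],
      sample = samples$sample[.data$si],
      genotype = samples$genotype[.data$si],
      replicate = samples$replicate[.data$si],
      ct = baseline[.data$ti] + samples$offset[.data$si] -
        ifelse(.data$genotype == "AD", shift[.data$ti], 0) +
        stats::rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    dplyr::select("target", "sample", "genotype", "replicate", "ct")
  list(ct = ct, truth = tibble::tibble(target = targets,
                                       direction = direction))
}

#' Run the full synthetic-data generator
#'
#' @param params A [simulation_params()] object.
#' @return A list: `params`, `proteome`, `psms`, `truth` (proteomics
#'   ground truth), `ct`, `ct_truth`.
#' @examples
#' sim <- simulate_study(simulation_params(n_proteins = 10, seed = 7))
#' names(sim)
#' @export
simulate_study <- function(params = simulation_params()) {
  proteome <- simulate_proteome(params)
  ms <- simulate_psm_tables(params, proteome)
  pcr <- simulate_ct_table(params)
  list(params = params, proteome = proteome, psms = ms$psms,
       truth = ms$truth, ct = pcr$ct, ct_truth = pcr$truth)
}

#' Write a simulated study to disk
#'
#' Emits `psm_rep<r>.tsv` (one PSM table per replicate),
#' `proteins.fasta`, `cts.tsv` and `truth.tsv` under `dir`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in sort(unique(sim$psms$replicate_id))) {
    write_psm_table(sim$psms[sim$psms$replicate_id == r, ],
                    file.path(dir, sprintf("psm_rep%d.tsv", r)))
  }
  write_protein_fasta(sim$proteome$db, file.path(dir, "proteins.fasta"))
  write_ct_table(sim$ct, file.path(dir, "cts.tsv"))
  truth <- dplyr::bind_rows(
    sim$truth,
    dplyr::mutate(sim$ct_truth, feature_id = .data$target, target = NULL,
                  region = NA_character_, level = "mirna")
  )
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
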