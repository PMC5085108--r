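mods_of_kind <- function(modifications, kinds) {
  lapply(parse_modifications(modifications),
         function(m) m[m$type %in% kinds, , drop = FALSE])
}

is_modified_feature <- function(modifications) {
  vapply(mods_of_kind(modifications, c("phospho", "deamidation")),
         nrow, 1L) > 0
}

#' Classify PTM features and map their sites onto proteins
#'
#' A feature carrying at least one deamidated Asn is a formerly
#' sialylated N-glycopeptide (`deglyco`; deamidation is the N->D scar
#' left by PNGase F removal of the glycan); otherwise a feature with at
#' least one phospho site on S/T/Y is `phospho`. Site positions are
#' translated to 1-based protein coordinates by exact substring search
#' of the peptide in its protein; if the peptide occurs more than once,
#' the lowest coordinate is used and a message records the tie.
#'
#' @param mat A feature intensity tibble (any scale state).
#' @param db Protein database (named character vector), used for site
#'   mapping; `NULL` skips mapping and leaves `site_positions` empty.
#' @return A tibble with one row per modified feature: `feature_id`,
#'   `protein_accession`, `feature_kind`, `peptide_sequence`,
#'   `modifications`, `site_positions` (list of protein coordinates),
#'   `n_sites`.
#' @export
ptm_features <- function(mat, db = NULL) {
  feats <- dplyr::distinct(
    mat, .data$feature_id, .data$peptide_sequence, .data$modifications,
    .data$protein_accession
  )
  feats <- feats[is_modified_feature(feats$modifications), ]
  mods <- mods_of_kind(feats$modifications, c("phospho", "deamidation"))
  kind <- vapply(mods, function(m) {
    if (any(m$type == "deamidation")) "deglyco" else "phospho"
  }, "")
  sites <- vector("list", nrow(feats))
  ties <- 0L
  for (i in seq_len(nrow(feats))) {
    m <- mods[[i]]
    m <- m[m$type == (if (kind[i] == "deglyco") "deamidation" else "phospho"), ]
    pep_pos <- m$position
    if (!is.null(db)) {
      seqs <- unname(db[feats$protein_accession[i]])
      if (is.na(seqs)) {
        sites[[i]] <- integer()
        next
      }
      hits <- gregexpr(feats$peptide_sequence[i], seqs, fixed = TRUE)[[1]]
      if (hits[1] == -1) {
        sites[[i]] <- integer()
      } else {
        if (length(hits) > 1) ties <- ties + 1L
        sites[[i]] <- sort(min(hits) - 1L + pep_pos)
      }
    } else {
      sites[[i]] <- sort(pep_pos)
    }
  }
  if (ties > 0) {
    message(ties, " peptide(s) matched their protein more than once; ",
            "lowest coordinate used")
  }
  tibble::tibble(
    feature_id = feats$feature_id,
    protein_accession = feats$protein_accession,
    feature_kind = kind,
    peptide_sequence = feats$peptide_sequence,
    modifications = feats$modifications,
    site_positions = sites,
    n_sites = lengths(sites)
  )
}

#' Roll up modified peptides into PTM features
#'
#' Merges peptide evidence for identical modified-peptide features by
#' the arithmetic mean of the member peptides' centered log2 values per
#' channel, within each replicate. Single-member groups
#' ("one-hit-wonders") are retained. By default the grouping is the
#' feature key itself (each modified peptide is its own feature); an
#' explicit `grouping` tibble (`feature_id` -> `group_id`) merges
#' several peptide variants into one feature.
#'
#' @param mat A mean-centered intensity tibble.
#' @param grouping Optional tibble with columns `feature_id`,
#'   `group_id`.
#' @return A mean-centered intensity tibble of PTM features (column
#'   `n_peptides` gives group sizes; `protein_accession` of the first
#'   member is carried along).
#' @export
rollup_ptm <- function(mat, grouping = NULL) {
  require_state(mat, "mean_centered")
  chan <- plex_channels()
  mat <- mat[is_modified_feature(mat$modifications), ]
  if (is.null(grouping)) {
    grouping <- tibble::tibble(feature_id = unique(mat$feature_id),
                               group_id = unique(mat$feature_id))
  }
  out <- mat |>
    dplyr::inner_join(grouping, by = "feature_id") |>
    dplyr::group_by(.data$group_id, .data$replicate_id) |>
    dplyr::summarise(
      peptide_sequence = .data$peptide_sequence[1],
      modifications = .data$modifications[1],
      protein_accession = .data$protein_accession[1],
      is_unique = all(.data$is_unique),
      n_peptides = dplyr::n(),
      dplyr::across(dplyr::all_of(chan),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::rename(feature_id = "group_id") |>
    dplyr::arrange(.data$replicate_id, .data$feature_id)
  set_scale_state(out, "mean_centered")
}

isoform_base <- function(accession) sub("-[0-9]+$", "", accession)

#' Remove proteoform-ambiguous evidence before protein rollup
#'
#' Drops peptides mapping to more than one protein entry (non-unique),
#' and collapses isoform accessions that are supported by an identical
#' peptide set (differing only by an `-N` isoform suffix) to the base
#' accession, removing the redundant proteoform entries.
#'
#' @param mat An intensity tibble.
#' @return The tibble with ambiguous evidence removed.
#' @export
remove_proteoforms <- function(mat) {
  n0 <- nrow(mat)
  mat <- mat[mat$is_unique, ]
  if (nrow(mat) < n0) {
    message(n0 - nrow(mat), " non-unique peptide row(s) removed")
  }
  pepsets <- mat |>
    dplyr::distinct(.data$protein_accession, .data$peptide_sequence) |>
    dplyr::group_by(.data$protein_accession) |>
    dplyr::summarise(
      set = paste(sort(.data$peptide_sequence), collapse = "|"),
      .groups = "drop"
    ) |>
    dplyr::mutate(base = isoform_base(.data$protein_accession))
  drop <- pepsets |>
    dplyr::group_by(.data$base, .data$set) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::arrange(.data$protein_accession, .by_group = TRUE) |>
    dplyr::slice(-1) |>
    dplyr::pull(.data$protein_accession)
  if (length(drop)) {
    message(length(drop), " proteoform accession(s) removed: ",
            paste(utils::head(drop, 5), collapse = ", "))
  }
  mat[!mat$protein_accession %in% drop, ]
}

#' Roll up unmodified peptides into proteins
#'
#' Uses only unmodified (no phospho, no deamidation), unique peptides,
#' after proteoform removal. Within each replicate, a protein's channel
#' intensity is the arithmetic mean of its contributing peptides'
#' centered log2 values. Proteins supported by at least two unique
#' peptides in a replicate enter the protein results; proteins with a
#' single peptide are emitted to a side table used only for normalizing
#' PTM ratios against protein expression.
#'
#' @param mat A mean-centered intensity tibble.
#' @return A list with two mean-centered protein intensity tibbles:
#'   `proteins` (>= 2 unique peptides) and `single_peptide` (exactly 1),
#'   each with columns `protein_accession`, `replicate_id`,
#'   `n_peptides` and the eight channels.
#' @export
rollup_protein <- function(mat) {
  require_state(mat, "mean_centered")
  chan <- plex_channels()
  mat <- mat[!is_modified_feature(mat$modifications), ]
  mat <- remove_proteoforms(mat)
  rolled <- mat |>
    dplyr::group_by(.data$protein_accession, .data$replicate_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$peptide_sequence),
      dplyr::across(dplyr::all_of(chan),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$replicate_id, .data$protein_accession)
  list(
    proteins = set_scale_state(rolled[rolled$n_peptides >= 2, ],
                               "mean_centered"),
    single_peptide = set_scale_state(rolled[rolled$n_peptides == 1, ],
                                     "mean_centered")
  )
}

#' Per-region AD/WT ratios across replicates
#'
#' For each feature and region, the per-replicate linear ratio is
#' `2^(x_AD - x_WT)` over the region's two channels; a replicate counts
#' as observed only if both channels are present. Summaries: arithmetic
#' mean of the available linear ratios (`mean_ratio`), and their
#' relative standard deviation `sd/mean` (`rel_sd`; `NA` with fewer
#' than two observations). Features observed in no replicate of a
#' region are dropped.
#'
#' @param mat A mean-centered feature, PTM-feature or protein intensity
#'   tibble. The id column is `feature_id` if present, else
#'   `protein_accession`.
#' @param design Channel design.
#' @param regions Regions to compute (default all four).
#' @param n_replicates Total number of biological replicates (used to
#'   lay out the per-replicate ratio columns).
#' @return A tibble with columns `feature_id`, `region`,
#'   `ratio_rep<r>` for each replicate, `n_observed`, `mean_ratio`,
#'   `rel_sd`, `normalized` (FALSE). Protein inputs carry
#'   `protein_accession` and `min_peptides` (the smallest per-replicate
#'   unique-peptide support) as well.
#' @export
compute_ratios <- function(mat, design = default_channel_design(),
                           regions = plex_regions(),
                           n_replicates = max(mat$replicate_id)) {
  require_state(mat, "mean_centered")
  validate_channel_design(design)
  id_col <- if ("feature_id" %in% names(mat)) "feature_id" else
    "protein_accession"
  has_acc <- "protein_accession" %in% names(mat)
  has_npep <- "n_peptides" %in% names(mat)
  out <- purrr::map_dfr(regions, function(rg) {
    ch_wt <- design$channel[design$region == rg & design$genotype == "WT"]
    ch_ad <- design$channel[design$region == rg & design$genotype == "AD"]
    df <- tibble::tibble(
      feature_id = mat[[id_col]],
      region = rg,
      replicate_id = mat$replicate_id,
      ratio = 2^(mat[[ch_ad]] - mat[[ch_wt]])
    )
    if (has_acc) df$protein_accession <- mat$protein_accession
    if (has_npep) df$n_peptides <- mat$n_peptides
    df
  })
  keep_cols <- c("feature_id", "region",
                 if (has_acc) "protein_accession")
  summ <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep_cols))) |>
    dplyr::summarise(
      n_observed = sum(!is.na(.data$ratio)),
      mean_ratio = mean(.data$ratio, na.rm = TRUE),
      rel_sd = ifelse(sum(!is.na(.data$ratio)) >= 2,
                      stats::sd(.data$ratio, na.rm = TRUE) /
                        mean(.data$ratio, na.rm = TRUE), NA_real_),
      min_peptides = if (has_npep) min(.data$n_peptides) else NA_integer_,
      .groups = "drop"
    )
  wide <- out |>
    dplyr::select("feature_id", "region", "replicate_id", "ratio") |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "ratio",
                       names_prefix = "ratio_rep")
  rep_cols <- paste0("ratio_rep", seq_len(n_replicates))
  for (rc in setdiff(rep_cols, names(wide))) wide[[rc]] <- NA_real_
  res <- dplyr::inner_join(summ, wide[, c("feature_id", "region", rep_cols)],
                           by = c("feature_id", "region")) |>
    dplyr::filter(.data$n_observed > 0) |>
    dplyr::mutate(normalized = FALSE) |>
    dplyr::relocate(dplyr::all_of(rep_cols), .after = "region") |>
    dplyr::arrange(.data$region, .data$feature_id)
  if (!has_npep) res$min_peptides <- NULL
  res
}

ratio_rep_cols <- function(ratios) {
  grep("^ratio_rep[0-9]+$", names(ratios), value = TRUE)
}

#' Recompute ratio summaries from per-replicate ratio columns
#'
#' Fills/updates `n_observed`, `mean_ratio` and `rel_sd` from the
#' `ratio_rep<r>` columns of a ratio tibble; used after any operation
#' that edits per-replicate ratios.
#'
#' @param ratios A ratio tibble with `ratio_rep<r>` columns.
#' @return The tibble with refreshed summary columns.
#' @export
summarise_ratio_rows <- function(ratios) {
  rep_cols <- ratio_rep_cols(ratios)
  vals <- as.matrix(ratios[rep_cols])
  n_obs <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, stats::sd, na.rm = TRUE)
  ratios$n_observed <- n_obs
  ratios$mean_ratio <- ifelse(n_obs > 0, m, NA_real_)
  ratios$rel_sd <- ifelse(n_obs >= 2, s / m, NA_real_)
  ratios
}

#' Normalize PTM ratios against protein expression
#'
#' Divides each PTM feature's per-replicate ratio by its protein's
#' ratio in the same replicate and region, so that a call reflects
#' change at the PTM level rather than protein abundance. Protein
#' ratios include the single-peptide side table. Replicates without a
#' protein quantification keep the un-normalized PTM ratio; the
#' `n_normalized` column counts how many replicates were normalized.
#' `mean_ratio` and `rel_sd` are recomputed on the normalized ratios.
#'
#' @param ptm_ratios Ratio tibble of PTM features (from
#'   [compute_ratios()] on a [rollup_ptm()] table); must carry
#'   `protein_accession`.
#' @param protein_ratios Ratio tibble of proteins (main and
#'   single-peptide tables combined).
#' @return The PTM ratio tibble with `normalized = TRUE` and
#'   `n_normalized` added.
#' @export
normalize_ptm_ratios <- function(ptm_ratios, protein_ratios) {
  stopifnot("protein_accession" %in% names(ptm_ratios))
  rep_cols <- ratio_rep_cols(ptm_ratios)
  prot <- protein_ratios[, c("feature_id", "region", rep_cols)]
  names(prot) <- c("protein_accession", "region",
                   paste0("prot_", rep_cols))
  joined <- dplyr::left_join(ptm_ratios, prot,
                             by = c("protein_accession", "region"))
  n_norm <- integer(nrow(joined))
  for (rc in rep_cols) {
    pr <- joined[[paste0("prot_", rc)]]
    if (any(!is.na(pr) & pr <= 0)) stop("non-positive protein ratio")
    use <- !is.na(pr) & !is.na(joined[[rc]])
    joined[[rc]][use] <- joined[[rc]][use] / pr[use]
    n_norm <- n_norm + as.integer(use)
    joined[[paste0("prot_", rc)]] <- NULL
  }
  joined$n_normalized <- n_norm
  joined$normalized <- TRUE
  summarise_ratio_rows(joined)
}

#' Check the N-linked glycosylation sequon
#'
#' True iff the consensus motif N-X-(S/T/C) with X != P holds at the
#' given 1-based Asn position of the protein: the two following
#' residues must exist, the next residue must not be Pro, and the one
#' after must be Ser, Thr or Cys. The site residue must be Asn, or Asp
#' for databases reflecting the deamidation (N->D) left by glycan
#' removal. Vectorized over `accession`/`asn_position`.
#'
#' @param db Protein database (named character vector).
#' @param accession Protein accession(s).
#' @param asn_position 1-based site position(s) within the protein.
#' @return Logical vector.
#' @examples
#' check_sequon(c(P1 = "MKNGSAA"), "P1", 3)   # N-G-S: TRUE
#' check_sequon(c(P1 = "MKNPTAA"), "P1", 3)   # N-P-T: FALSE
#' @export
check_sequon <- function(db, accession, asn_position) {
  n <- max(length(accession), length(asn_position))
  accession <- rep_len(accession, n)
  asn_position <- rep_len(asn_position, n)
  vapply(seq_len(n), function(i) {
    seqs <- unname(db[accession[i]])
    if (is.na(seqs)) stop("unknown accession: ", accession[i])
    p <- asn_position[i]
    if (is.na(p) || p < 1 || p > nchar(seqs)) {
      stop("site position ", p, " out of range for ", accession[i])
    }
    site <- substr(seqs, p, p)
    if (!site %in% c("N", "D")) {
      stop("residue at position ", p, " of ", accession[i],
           " is ", site, ", not N (or deamidated D)")
    }
    if (p + 2 > nchar(seqs)) return(FALSE)
    x1 <- substr(seqs, p + 1, p + 1)
    x2 <- substr(seqs, p + 2, p + 2)
    x1 != "P" && x2 %in% c("S", "T", "C")
  }, logical(1))
}

#' Call deregulated features
#'
#' Applies the deregulation criteria to a finalized ratio table:
#' \enumerate{
#'   \item presence: observed in at least `n - 1` replicates (both of
#'     the region's channels present); proteins additionally need their
#'     two-unique-peptide identification in the replicates counted;
#'   \item reproducibility: relative standard deviation of the
#'     per-replicate ratios <= 30\%;
#'   \item effect size: mean ratio >= 1.30 (up) or <= 0.77 (down),
#'     boundaries inclusive;
#'   \item for deglyco features, a valid N-glycosylation sequon.
#' }
#' `direction` is `up`/`down` only when every applicable flag holds,
#' else `none`.
#'
#' @param ratios A ratio tibble ([compute_ratios()], optionally
#'   [normalize_ptm_ratios()]). If a `sequon_ok` column is present it
#'   participates in the call; otherwise it is treated as satisfied.
#' @param thresholds A [default_thresholds()] object.
#' @param n_replicates Total number of biological replicates.
#' @return The input with logical columns `presence_ok`, `sd_ok`,
#'   `ratio_ok`, `sequon_ok` and a `direction` factor column added.
#' @examples
#' r <- tibble::tibble(feature_id = "f", region = "neocortex",
#'                     ratio_rep1 = 1.35, ratio_rep2 = 1.32,
#'                     ratio_rep3 = 1.40)
#' call_deregulation(summarise_ratio_rows(r), n_replicates = 3)$direction
#' @export
call_deregulation <- function(ratios, thresholds = default_thresholds(),
                              n_replicates = 3) {
  t <- thresholds
  min_rep <- if (is.na(t$min_replicates)) n_replicates - 1L else
    t$min_replicates
  presence <- ratios$n_observed >= min_rep
  if ("min_peptides" %in% names(ratios)) {
    presence <- presence & ratios$min_peptides >= 2
  }
  sd_ok <- !is.na(ratios$rel_sd) & ratios$rel_sd <= t$sd_max_fraction
  up <- !is.na(ratios$mean_ratio) & ratios$mean_ratio >= t$ratio_up
  down <- !is.na(ratios$mean_ratio) & ratios$mean_ratio <= t$ratio_down
  sequon <- if ("sequon_ok" %in% names(ratios)) {
    !is.na(ratios$sequon_ok) & ratios$sequon_ok
  } else rep(TRUE, nrow(ratios))
  all_ok <- presence & sd_ok & sequon
  ratios$presence_ok <- presence
  ratios$sd_ok <- sd_ok
  ratios$ratio_ok <- up | down
  ratios$sequon_ok <- sequon
  ratios$direction <- factor(
    ifelse(all_ok & up, "up", ifelse(all_ok & down, "down", "none")),
    levels = c("up", "down", "none")
  )
  ratios
}
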