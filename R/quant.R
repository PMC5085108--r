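scale_states <- function() c("raw_log2", "median_normalized", "mean_centered")

#' Scale state of an intensity table
#'
#' Intensity tables move monotonically through the states
#' `raw_log2 -> median_normalized -> mean_centered`; each normalization
#' step checks the incoming state and advances it.
#'
#' @param x An intensity tibble produced by [psm_to_log2()] and friends.
#' @return The state string.
#' @export
scale_state <- function(x) {
  st <- attr(x, "scale_state", exact = TRUE)
  if (is.null(st)) stop("not an intensity table: no scale_state attribute")
  st
}

set_scale_state <- function(x, state) {
  state <- match.arg(state, scale_states())
  old <- attr(x, "scale_state", exact = TRUE)
  if (!is.null(old) &&
      match(state, scale_states()) < match(old, scale_states())) {
    stop("scale_state may only advance (", old, " -> ", state, ")")
  }
  attr(x, "scale_state") <- state
  x
}

require_state <- function(x, state) {
  if (scale_state(x) != state) {
    stop("expected an intensity table in state '", state, "', got '",
         scale_state(x), "'")
  }
  invisible(x)
}

#' Filter peptide-spectrum matches on search-engine confidence
#'
#' Keeps PSMs that satisfy all of: rank 1; percolator q-value <= 0.01;
#' Mascot ion score >= 22; Sequest delta-Cn >= 0.1; Sequest Xcorr
#' strictly greater than the charge-specific bound (1.5 / 2 / 2.25 / 2.5
#' for charges +1..+4; higher charges use the +4 bound); and at most one
#' missed cleavage. A missing score fails its criterion. Records with a
#' non-positive charge are rejected with a diagnostic warning. Input
#' order is preserved and the filter is idempotent.
#'
#' @param psms A PSM tibble (see [read_psm_table()]).
#' @param thresholds A [default_thresholds()] object.
#' @return The kept rows, in input order.
#' @examples
#' psms <- simulate_study(simulation_params(n_proteins = 5, seed = 1))$psms
#' nrow(filter_psms(psms, default_thresholds()))
#' @export
filter_psms <- function(psms, thresholds = default_thresholds()) {
  validate_psm_table(psms)
  t <- thresholds
  bad_charge <- !is.na(psms$charge) & psms$charge <= 0
  if (any(bad_charge)) {
    warning(sum(bad_charge), " PSM(s) rejected for non-positive charge")
  }
  charge_key <- pmin(pmax(psms$charge, 1L),
                     max(as.integer(names(t$xcorr_min_by_charge))))
  xcorr_bound <- unname(t$xcorr_min_by_charge[as.character(charge_key)])
  ok <- !bad_charge &
    !is.na(psms$rank) & psms$rank == 1L &
    !is.na(psms$percolator_q) & psms$percolator_q <= t$percolator_q_max &
    !is.na(psms$mascot_score) & psms$mascot_score >= t$mascot_min &
    !is.na(psms$sequest_dcn) & psms$sequest_dcn >= t$dcn_min &
    !is.na(psms$sequest_xcorr) & psms$sequest_xcorr > xcorr_bound &
    !is.na(psms$missed_cleavages) &
    psms$missed_cleavages <= t$max_missed_cleavages
  ok[is.na(ok)] <- FALSE
  psms[ok, ]
}

#' Feature key of a peptide
#'
#' A quantification feature is an identical modified peptide: the same
#' sequence carrying the same modification set.
#'
#' @param sequence,modifications Character vectors.
#' @return Character feature keys.
#' @export
feature_key <- function(sequence, modifications) {
  mods <- canonical_modifications(modifications)
  ifelse(nzchar(mods), paste0(sequence, "/", mods), sequence)
}

#' Convert PSM reporter intensities to log2 feature intensities
#'
#' Groups PSMs by feature (peptide sequence + modification set) within
#' each replicate; multiple PSMs of the same feature are aggregated per
#' channel by the median of their raw intensities (robust to outlier
#' spectra) before taking log2. Zero or negative intensities become
#' missing with a warning.
#'
#' @param psms A (filtered) PSM tibble covering one or more replicates.
#' @return An intensity tibble in state `raw_log2`: one row per
#'   (feature, replicate) with columns `feature_id`, `peptide_sequence`,
#'   `modifications`, `protein_accession`, `is_unique`, `replicate_id`
#'   and the eight channel columns.
#' @export
psm_to_log2 <- function(psms) {
  validate_psm_table(psms)
  chan <- plex_channels()
  nonpos <- sum(as.matrix(psms[chan]) <= 0, na.rm = TRUE)
  if (nonpos > 0) {
    warning(nonpos, " non-positive intensit",
            if (nonpos == 1) "y" else "ies", " set to missing")
  }
  psms <- dplyr::mutate(psms, dplyr::across(
    dplyr::all_of(chan), ~ ifelse(!is.na(.x) & .x <= 0, NA_real_, .x)
  ))
  out <- psms |>
    dplyr::mutate(
      feature_id = feature_key(.data$peptide_sequence, .data$modifications)
    ) |>
    dplyr::group_by(.data$feature_id, .data$replicate_id) |>
    dplyr::summarise(
      peptide_sequence = .data$peptide_sequence[1],
      modifications = canonical_modifications(.data$modifications[1]),
      protein_accession = .data$protein_accession[1],
      is_unique = all(.data$is_unique),
      dplyr::across(dplyr::all_of(chan),
                    ~ if (all(is.na(.x))) NA_real_ else
                      log2(stats::median(.x, na.rm = TRUE))),
      .groups = "drop"
    ) |>
    dplyr::select("feature_id", "peptide_sequence", "modifications",
                  "protein_accession", "is_unique", "replicate_id",
                  dplyr::all_of(chan)) |>
    dplyr::arrange(.data$replicate_id, .data$feature_id)
  set_scale_state(out, "raw_log2")
}

#' Median-normalize channel intensities
#'
#' For every channel within every replicate, subtracts the median of the
#' channel's non-missing log2 values, so each channel's post-
#' normalization median is zero. This corrects unequal channel loading
#' of the 8-plex mix. Idempotent.
#'
#' @param mat An intensity tibble in state `raw_log2` (or already
#'   `median_normalized`, in which case it is re-normalized, a no-op).
#' @return The tibble in state `median_normalized`.
#' @export
median_normalize <- function(mat) {
  if (!scale_state(mat) %in% c("raw_log2", "median_normalized")) {
    stop("median_normalize expects raw_log2 input")
  }
  chan <- plex_channels()
  out <- mat |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(chan), function(x) {
      if (all(is.na(x))) {
        stop("channel entirely missing within a replicate")
      }
      x - stats::median(x, na.rm = TRUE)
    })) |>
    dplyr::ungroup()
  set_scale_state(out, "median_normalized")
}

#' Mean-center each feature across the experimental conditions
#'
#' Subtracts from each feature row the mean of its non-missing channel
#' values, so replicates become comparable and can be merged: after
#' centering, a feature's non-missing row mean is zero in every
#' replicate. Within-row channel differences -- and hence all AD/WT
#' ratios -- are unchanged. Rows with fewer than 2 non-missing channels
#' are dropped with a warning.
#'
#' @param mat An intensity tibble in state `median_normalized`.
#' @return The tibble in state `mean_centered`.
#' @export
center_features <- function(mat) {
  require_state(mat, "median_normalized")
  chan <- plex_channels()
  vals <- as.matrix(mat[chan])
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs < 2)) {
    warning(sum(n_obs < 2), " feature row(s) with < 2 observed channels dropped")
    mat <- mat[n_obs >= 2, ]
    vals <- vals[n_obs >= 2, , drop = FALSE]
  }
  centered <- vals - rowMeans(vals, na.rm = TRUE)
  mat[chan] <- tibble::as_tibble(centered)
  attr(mat, "scale_state") <- "median_normalized"
  set_scale_state(mat, "mean_centered")
}

#' Principal-component analysis of channel samples
#'
#' Treats every (channel, replicate) combination as an observation over
#' the features shared by all samples (features missing anywhere are
#' dropped with a message) and computes an unscaled PCA of the centered
#' data. Component signs are canonicalized so the largest-magnitude
#' loading of each component is positive. Used as a sample-quality
#' check: with a genuine genotype effect, WT and AD samples of a region
#' separate.
#'
#' @param mat An intensity tibble in state `mean_centered` (any earlier
#'   state is accepted; centering state only affects the feature
#'   offsets, not sample separation).
#' @param design Channel design used to annotate the scores.
#' @return An object of class `plex_pca` with elements `scores` (tibble:
#'   sample annotation + PC columns), `explained_variance` (fractions,
#'   non-increasing), `rotation`, `sdev`, `n_features`.
#' @export
run_pca <- function(mat, design = default_channel_design()) {
  validate_channel_design(design)
  chan <- plex_channels()
  wide <- mat |>
    dplyr::select("feature_id", "replicate_id", dplyr::all_of(chan)) |>
    tidyr::pivot_longer(dplyr::all_of(chan), names_to = "channel",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = c("channel", "replicate_id"),
                       values_from = "value", names_sep = "_r")
  complete <- stats::complete.cases(wide[, -1])
  if (sum(!complete) > 0) {
    message(sum(!complete), " feature(s) incomplete across samples dropped for PCA")
  }
  wide <- wide[complete, ]
  if (nrow(wide) < 2) stop("fewer than 2 complete features; cannot run PCA")
  x <- t(as.matrix(wide[, -1]))   # samples x features
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # canonical signs: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ids <- strsplit(rownames(x), "_r", fixed = TRUE)
  scores <- tibble::tibble(
    sample = rownames(x),
    channel = vapply(ids, `[`, "", 1L),
    replicate_id = as.integer(vapply(ids, `[`, "", 2L))
  ) |>
    dplyr::left_join(design, by = "channel") |>
    dplyr::bind_cols(tibble::as_tibble(pc$x))
  structure(
    list(scores = scores, explained_variance = ev,
         rotation = pc$rotation, sdev = pc$sdev, n_features = nrow(wide)),
    class = "plex_pca"
  )
}

#' @export
print.plex_pca <- function(x, ...) {
  cat("<plex_pca> ", nrow(x$scores), " samples, ", x$n_features,
      " features\n", sep = "")
  cat("  explained variance: ",
      paste0(round(100 * utils::head(x$explained_variance, 4), 1), "%",
             collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Genotype-separation silhouette of a PCA
#'
#' For each region, computes the mean silhouette width of its channel
#' samples grouped by genotype, in the space of the first `n_components`
#' principal-component scores. Positive values mean WT and AD samples
#' of that region form separated groups.
#'
#' @param pca A `plex_pca` object.
#' @param n_components Number of leading components to use.
#' @return A tibble with columns `region`, `silhouette`.
#' @export
pca_genotype_silhouette <- function(pca, n_components = 2) {
  pcs <- paste0("PC", seq_len(min(n_components,
                                  length(pca$explained_variance))))
  pca$scores |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(df, key) {
      labels <- as.integer(factor(df$genotype))
      d <- stats::dist(as.matrix(df[, pcs]))
      sil <- cluster::silhouette(labels, d)
      tibble::tibble(silhouette = mean(sil[, "sil_width"]))
    }) |>
    dplyr::ungroup()
}
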