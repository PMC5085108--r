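#' Delta-Ct normalization against the median of all targets
#'
#' For every sample, subtracts the median Ct over all non-missing
#' targets of that sample: `dCt(target, sample) = Ct - median(Ct of
#' sample)`. This removes per-sample (plate/loading) offsets, so adding
#' a constant to all Cts of a sample leaves dCt unchanged. Requires at
#' least three targets per sample for the median to be meaningful; a
#' sample with no observed Ct at all is an error.
#'
#' @param ct A long Ct tibble (see [read_ct_table()]): columns `target`,
#'   `sample`, `genotype`, `replicate`, `ct`.
#' @return The tibble with a `delta_ct` column added.
#' @export
delta_ct <- function(ct) {
  counts <- ct |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_targets = dplyr::n(),
                     n_obs = sum(!is.na(.data$ct)), .groups = "drop")
  if (any(counts$n_obs == 0)) {
    stop("sample(s) with all-missing Ct: ",
         paste(counts$sample[counts$n_obs == 0], collapse = ", "))
  }
  if (any(counts$n_targets < 3)) {
    stop("fewer than 3 targets per sample; median normalization unreliable")
  }
  ct |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(delta_ct = .data$ct -
                    stats::median(.data$ct, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' 2^-ddCt fold changes with t-tests
#'
#' For each target: `ddCt = mean dCt(AD) - mean dCt(WT)`, linear fold
#' change `2^-ddCt`, and the signed fold-change convention in which
#' values below 1 are reported as negative reciprocals (0.5 -> -2), so
#' `|fold_change_signed| >= 1` always. The p-value is a two-sided
#' unpaired Student t-test (pooled variance) on the per-replicate dCt
#' values. Targets with fewer than two observed replicates in either
#' genotype are skipped with a warning.
#'
#' @param dct Output of [delta_ct()].
#' @return A tibble with columns `target`, `n_wt`, `n_ad`, `ddct`,
#'   `fold_change_linear`, `fold_change_signed`, `p_value`.
#' @export
ddct_fold_change <- function(dct) {
  res <- dct |>
    dplyr::filter(!is.na(.data$delta_ct)) |>
    dplyr::group_by(.data$target) |>
    dplyr::group_modify(function(df, key) {
      wt <- df$delta_ct[df$genotype == "WT"]
      ad <- df$delta_ct[df$genotype == "AD"]
      if (length(wt) < 2 || length(ad) < 2) {
        return(tibble::tibble(n_wt = length(wt), n_ad = length(ad),
                              ddct = NA_real_,
                              fold_change_linear = NA_real_,
                              fold_change_signed = NA_real_,
                              p_value = NA_real_))
      }
      ddct <- mean(ad) - mean(wt)
      fc <- 2^(-ddct)
      # degenerate (numerically constant) groups: the test statistic is
      # undefined; report 1 for no difference, 0 for a clean separation
      p <- tryCatch(stats::t.test(ad, wt, var.equal = TRUE)$p.value,
                    error = function(e) {
                      if (isTRUE(all.equal(mean(ad), mean(wt)))) 1 else 0
                    })
      tibble::tibble(
        n_wt = length(wt), n_ad = length(ad), ddct = ddct,
        fold_change_linear = fc,
        fold_change_signed = ifelse(fc >= 1, fc, -1 / fc),
        p_value = p
      )
    }) |>
    dplyr::ungroup()
  skipped <- res$target[is.na(res$ddct)]
  if (length(skipped)) {
    warning(length(skipped), " target(s) skipped (fewer than 2 replicates ",
            "in a genotype): ", paste(utils::head(skipped, 5), collapse = ", "))
  }
  res[!is.na(res$ddct), ]
}

#' Call differentially expressed qPCR targets
#'
#' A target is `up` if `p <= 0.05` and signed fold-change `>= 1.2`,
#' `down` if `p <= 0.05` and signed fold-change `<= -1.2`, else `none`
#' (boundaries inclusive). No multiple-testing correction is applied by
#' default; `fdr = TRUE` additionally computes Benjamini-Hochberg
#' adjusted p-values and uses them for the call.
#'
#' @param results Output of [ddct_fold_change()].
#' @param thresholds A [default_thresholds()] object (`pcr_fc`, `pcr_p`).
#' @param fdr Use Benjamini-Hochberg adjusted p-values for the call.
#' @return The input with a `direction` factor column (and `p_adjusted`
#'   when `fdr = TRUE`) added.
#' @export
call_pcr <- function(results, thresholds = default_thresholds(),
                     fdr = FALSE) {
  p <- results$p_value
  if (fdr) {
    results$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  sig <- !is.na(p) & p <= thresholds$pcr_p
  results$direction <- factor(
    ifelse(sig & results$fold_change_signed >= thresholds$pcr_fc, "up",
           ifelse(sig & results$fold_change_signed <= -thresholds$pcr_fc,
                  "down", "none")),
    levels = c("up", "down", "none")
  )
  results
}

#' Full qPCR array analysis
#'
#' Convenience wrapper: median-of-targets normalization, 2^-ddCt fold
#' changes with t-tests, and threshold calling.
#'
#' @inheritParams delta_ct
#' @inheritParams call_pcr
#' @return The called result tibble (see [call_pcr()]).
#' @export
analyze_pcr_array <- function(ct, thresholds = default_thresholds(),
                              fdr = FALSE) {
  ct |> delta_ct() |> ddct_fold_change() |> call_pcr(thresholds, fdr = fdr)
}
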