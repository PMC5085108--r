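#' Exact Venn cell counts for deregulated sets
#'
#' Given 2-4 named sets of feature identifiers (one per region),
#' computes the exact count and member list of every non-empty-by-
#' construction Venn cell (all `2^k - 1` region combinations,
#' exclusive: a member is counted in the cell of exactly the regions
#' containing it). Duplicates within a set are removed with a warning.
#' Cell counts over the disjoint cells sum to the union size, and are
#' invariant to region order.
#'
#' @param sets Named list of character vectors.
#' @return A tibble with columns `cell` (region names joined by `&`),
#'   `degree` (number of regions in the cell), `count`, `members`
#'   (list-column, sorted).
#' @examples
#' venn_counts(list(A = c("x", "y"), B = "y"))
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)), all(nzchar(names(sets))))
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("duplicate feature(s) within set(s) ",
            paste(names(sets)[dup], collapse = ", "), "; deduplicated")
    sets <- lapply(sets, unique)
  }
  k <- length(sets)
  nms <- names(sets)
  all_members <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) all_members %in% s,
                       logical(length(all_members)))
  if (length(all_members) == 1) membership <- matrix(membership, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- nms
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    mask <- unlist(combos[i, ])
    inside <- if (length(all_members)) {
      apply(membership, 1, function(m) all(m == mask))
    } else logical(0)
    tibble::tibble(
      cell = paste(nms[mask], collapse = "&"),
      degree = sum(mask),
      count = sum(inside),
      members = list(all_members[inside])
    )
  }) |>
    dplyr::arrange(.data$degree, .data$cell)
}

#' Members shared by every set
#'
#' Convenience accessor for the full (k-way) intersection, regardless
#' of membership in-between: features present in all sets.
#'
#' @param sets Named list of character vectors.
#' @return Sorted character vector.
#' @export
shared_members <- function(sets) {
  sort(Reduce(intersect, lapply(sets, unique)))
}

#' Per-region fractions of deregulated features in a protein class
#'
#' Against a user-supplied class annotation (e.g. an exported protein-
#' class table), reports per region how many deregulated features carry
#' a given class label, as a count and a percentage of all deregulated
#' features in that region (1 decimal). Regions with an empty
#' deregulated set get a missing fraction.
#'
#' @param features A tibble with columns `region`, `feature_id` (the
#'   deregulated features per region).
#' @param annotation A tibble with columns `feature_id`, `class`
#'   (multiple rows per feature allowed; unannotated features allowed).
#' @param class_label The class to summarise.
#' @param regions Regions to report; regions with an empty deregulated
#'   set get `n_total = 0` and a missing fraction. Default: the regions
#'   present in `features`.
#' @return A tibble with columns `region`, `n_class`, `n_total`,
#'   `fraction`, `percent` (rounded to 1 decimal).
#' @export
class_fractions <- function(features, annotation, class_label,
                            regions = unique(features$region)) {
  stopifnot(all(c("region", "feature_id") %in% names(features)),
            all(c("feature_id", "class") %in% names(annotation)))
  in_class <- unique(annotation$feature_id[annotation$class == class_label])
  features |>
    dplyr::distinct(.data$region, .data$feature_id) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_class = sum(.data$feature_id %in% in_class),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(region = regions), by = "region") |>
    dplyr::mutate(
      n_class = dplyr::coalesce(.data$n_class, 0L),
      n_total = dplyr::coalesce(.data$n_total, 0L),
      fraction = ifelse(.data$n_total > 0,
                        .data$n_class / .data$n_total, NA_real_),
      percent = round(100 * .data$fraction, 1)
    ) |>
    dplyr::arrange(.data$region)
}

format_tsv_chunk <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1, function(r) paste(format(r, trim = TRUE), collapse = "\t")))
}

#' Build a combined run report
#'
#' Renders a deterministic markdown report (no timestamps) covering the
#' thresholds used, per-region deregulation tables, Venn overlap
#' counts, and qPCR calls. Sections for absent inputs state "no calls".
#'
#' @param protein_calls,ptm_calls Called ratio tibbles (or `NULL`).
#' @param pcr_calls Called qPCR tibble (or `NULL`).
#' @param thresholds The [default_thresholds()] object used.
#' @param pca A `plex_pca` object (or `NULL`); its explained variances
#'   are tabulated.
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines, invisibly if `path` is
#'   given.
#' @export
build_report <- function(protein_calls = NULL, ptm_calls = NULL,
                         pcr_calls = NULL,
                         thresholds = default_thresholds(),
                         pca = NULL, path = NULL) {
  lines <- c("# 8-plex quantification run report", "")
  lines <- c(lines, "## Thresholds", "")
  for (nm in names(thresholds)) {
    lines <- c(lines, paste0("- ", nm, ": ",
                             paste(thresholds[[nm]], collapse = " ")))
  }
  section <- function(title, calls, id_col = "feature_id") {
    out <- c("", paste0("## ", title), "")
    if (is.null(calls) || nrow(calls) == 0) return(c(out, "no calls"))
    hits <- calls[calls$direction != "none", ]
    if (nrow(hits) == 0) return(c(out, "no calls"))
    tab <- hits |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(up = sum(.data$direction == "up"),
                       down = sum(.data$direction == "down"),
                       .groups = "drop")
    out <- c(out, format_tsv_chunk(tab), "")
    sets <- split(hits[[id_col]], hits$region)
    if (length(sets) >= 2) {
      vc <- venn_counts(sets)
      out <- c(out, "### Overlap (Venn cells)", "",
               format_tsv_chunk(vc[, c("cell", "degree", "count")]))
    }
    out
  }
  lines <- c(lines, section("Deregulated proteins", protein_calls))
  lines <- c(lines, section("Deregulated PTM features", ptm_calls))
  lines <- c(lines, "", "## qPCR calls", "")
  if (is.null(pcr_calls) || sum(pcr_calls$direction != "none") == 0) {
    lines <- c(lines, "no calls")
  } else {
    hits <- pcr_calls[pcr_calls$direction != "none",
                      c("target", "fold_change_signed", "p_value",
                        "direction")]
    hits$fold_change_signed <- round(hits$fold_change_signed, 2)
    hits$p_value <- signif(hits$p_value, 3)
    lines <- c(lines, format_tsv_chunk(hits))
  }
  if (!is.null(pca)) {
    lines <- c(lines, "", "## PCA explained variance", "",
               paste0("- PC", seq_along(pca$explained_variance), ": ",
                      round(100 * pca$explained_variance, 1), "%"))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
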