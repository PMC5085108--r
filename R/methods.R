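#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCA result
#'
#' One row per (sample, component): sample annotation, score, and the
#' component's explained-variance fraction.
#'
#' @param x A `plex_pca` object.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `channel`, `replicate_id`,
#'   `region`, `genotype`, `component`, `score`,
#'   `explained_variance_fraction`.
#' @method tidy plex_pca
#' @export
tidy.plex_pca <- function(x, ...) {
  pcs <- paste0("PC", seq_along(x$explained_variance))
  x$scores |>
    tidyr::pivot_longer(dplyr::all_of(pcs), names_to = "component",
                        values_to = "score") |>
    dplyr::mutate(explained_variance_fraction =
                    x$explained_variance[as.integer(sub("PC", "",
                                                        .data$component))])
}

#' Glance at a PCA result
#'
#' @param x A `plex_pca` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `n_features`, `var_pc1`,
#'   `var_pc2`.
#' @method glance plex_pca
#' @export
glance.plex_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_features = x$n_features,
    var_pc1 = x$explained_variance[1],
    var_pc2 = x$explained_variance[2]
  )
}

#' Score plot of a sample-quality PCA
#'
#' PC1 vs PC2, coloured by region and shaped by genotype, with
#' explained-variance percentages on the axes.
#'
#' @param object A `plex_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plex_pca
#' @export
autoplot.plex_pca <- function(object, ...) {
  ev <- round(100 * object$explained_variance[1:2], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$region,
                               shape = .data$genotype)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Ratio/variability plot of deregulation calls
#'
#' Mean AD/WT ratio (log2 axis) against relative SD per feature and
#' region, coloured by call direction, with the fold-change and SD
#' cut-offs drawn.
#'
#' @param calls A called ratio tibble from [call_deregulation()].
#' @param thresholds The thresholds used (for the guide lines).
#' @return A ggplot.
#' @export
plot_deregulation <- function(calls, thresholds = default_thresholds()) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$mean_ratio, y = .data$rel_sd,
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(thresholds$ratio_down,
                                       thresholds$ratio_up),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$sd_max_fraction,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "mean AD/WT ratio", y = "relative SD") +
    ggplot2::theme_minimal()
}

#' Fold-change plot of qPCR calls
#'
#' Signed fold change per target against -log10 p, coloured by call.
#'
#' @param results A called qPCR tibble from [call_pcr()].
#' @param thresholds The thresholds used.
#' @return A ggplot.
#' @export
plot_pcr <- function(results, thresholds = default_thresholds()) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$fold_change_signed,
                               y = -log10(.data$p_value),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-thresholds$pcr_fc,
                                       thresholds$pcr_fc),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$pcr_p),
                        linetype = "dashed") +
    ggplot2::labs(x = "signed fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
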