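#' Reporter channels of the 8-plex design
#'
#' The eight iTRAQ 8-plex reporter-ion channel labels, in mass order.
#' Channel 120 does not exist in the 8-plex chemistry, hence the jump
#' from 119 to 121.
#'
#' @return Character vector of the eight channel labels.
#' @export
plex_channels <- function() {
  c("113", "114", "115", "116", "117", "118", "119", "121")
}

#' Brain regions of the study design
#'
#' @return Character vector of the four region labels.
#' @export
plex_regions <- function() {
  c("hippocampus", "neocortex", "olfactory_bulb", "brainstem")
}

#' Default channel-to-sample design
#'
#' Maps each reporter channel to a (region, genotype) pair: four brain
#' regions, each with a wild-type (WT) and a transgenic amyloidosis (AD)
#' sample, multiplexed into one 8-plex labelling. The default follows the
#' standard layout: 113 = hippocampus/WT, 114 = hippocampus/AD,
#' 115 = neocortex/WT, 116 = neocortex/AD, 117 = olfactory bulb/WT,
#' 118 = olfactory bulb/AD, 119 = brainstem/WT, 121 = brainstem/AD.
#'
#' @return A tibble with columns `channel`, `region`, `genotype`.
#' @examples
#' default_channel_design()
#' @export
default_channel_design <- function() {
  tibble::tibble(
    channel  = plex_channels(),
    region   = rep(plex_regions(), each = 2),
    genotype = rep(c("WT", "AD"), times = 4)
  )
}

#' Validate a channel design
#'
#' @param design A tibble with columns `channel`, `region`, `genotype`.
#' @return The design, invisibly, after validation.
#' @export
validate_channel_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("channel", "region", "genotype") %in% names(design)))
  if (!setequal(design$channel, plex_channels()) ||
      nrow(design) != length(plex_channels())) {
    stop("design must assign exactly the 8 channels ",
         paste(plex_channels(), collapse = ", "))
  }
  pairs <- paste(design$region, design$genotype)
  if (anyDuplicated(pairs)) {
    stop("each (region, genotype) pair must appear exactly once")
  }
  if (!all(design$genotype %in% c("WT", "AD"))) {
    stop("genotype must be 'WT' or 'AD'")
  }
  invisible(design)
}

#' Analysis thresholds
#'
#' Bundles every cut-off used by the pipeline. Defaults are the standard
#' operating points for this workflow:
#' \describe{
#'   \item{mascot_min}{Minimum Mascot ion score (22, inclusive).}
#'   \item{percolator_q_max}{Maximum percolator q-value (0.01, inclusive).}
#'   \item{dcn_min}{Minimum Sequest HT delta-Cn (0.1, inclusive).}
#'   \item{xcorr_min_by_charge}{Charge-specific Sequest Xcorr bounds
#'     (1.5 / 2 / 2.25 / 2.5 for +1..+4, strict: the score must exceed the
#'     bound; charges above +4 use the +4 bound).}
#'   \item{max_missed_cleavages}{Maximum tryptic missed cleavages (1).}
#'   \item{ratio_up, ratio_down}{Fold-change bounds for a deregulation
#'     call on AD/WT ratios (>= 1.30 up, <= 0.77 down, inclusive).}
#'   \item{sd_max_fraction}{Maximum relative standard deviation of
#'     per-replicate ratios (0.30).}
#'   \item{min_replicates}{Minimum replicates a feature must be observed
#'     in; `NA` means n - 1 of the available replicates.}
#'   \item{pcr_fc}{Signed fold-change bound for qPCR calls (1.2).}
#'   \item{pcr_p}{p-value bound for qPCR calls (0.05, inclusive).}
#' }
#'
#' @param mascot_min,percolator_q_max,dcn_min,xcorr_min_by_charge,max_missed_cleavages
#'   PSM confidence cut-offs, see Details.
#' @param ratio_up,ratio_down,sd_max_fraction,min_replicates Deregulation
#'   cut-offs, see Details.
#' @param pcr_fc,pcr_p qPCR cut-offs, see Details.
#' @return An object of class `plex_thresholds` (a named list).
#' @examples
#' t <- default_thresholds()
#' t$ratio_up
#' @export
default_thresholds <- function(mascot_min = 22,
                               percolator_q_max = 0.01,
                               dcn_min = 0.1,
                               xcorr_min_by_charge = c(`1` = 1.5, `2` = 2,
                                                       `3` = 2.25, `4` = 2.5),
                               max_missed_cleavages = 1,
                               ratio_up = 1.30,
                               ratio_down = 0.77,
                               sd_max_fraction = 0.30,
                               min_replicates = NA_integer_,
                               pcr_fc = 1.2,
                               pcr_p = 0.05) {
  stopifnot(ratio_down < 1, ratio_up > 1,
            all(c(mascot_min, dcn_min, xcorr_min_by_charge, ratio_up,
                  ratio_down, sd_max_fraction, pcr_fc, pcr_p) >= 0))
  structure(
    list(
      mascot_min = mascot_min,
      percolator_q_max = percolator_q_max,
      dcn_min = dcn_min,
      xcorr_min_by_charge = xcorr_min_by_charge,
      max_missed_cleavages = max_missed_cleavages,
      ratio_up = ratio_up,
      ratio_down = ratio_down,
      sd_max_fraction = sd_max_fraction,
      min_replicates = min_replicates,
      pcr_fc = pcr_fc,
      pcr_p = pcr_p
    ),
    class = "plex_thresholds"
  )
}

#' @export
print.plex_thresholds <- function(x, ...) {
  cat("<plex_thresholds>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Read thresholds and channel design from a YAML config file
#'
#' The config may contain a `thresholds:` block (any subset of the
#' [default_thresholds()] fields) and a `design:` block mapping channel
#' labels to `region`/`genotype` pairs. Missing entries fall back to the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `thresholds` and `design`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- default_thresholds()
  for (nm in names(cfg$thresholds)) {
    if (!nm %in% names(th)) stop("unknown threshold field: ", nm)
    val <- cfg$thresholds[[nm]]
    if (nm == "xcorr_min_by_charge") val <- unlist(val)
    th[[nm]] <- val
  }
  design <- default_channel_design()
  if (!is.null(cfg$design)) {
    design <- purrr::imap_dfr(cfg$design, function(x, ch) {
      tibble::tibble(channel = as.character(ch),
                     region = x$region, genotype = x$genotype)
    })
    validate_channel_design(design)
  }
  list(thresholds = th, design = design)
}

#' Write thresholds and channel design to a YAML config file
#'
#' @param thresholds A `plex_thresholds` object.
#' @param design A channel design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(thresholds, design, path) {
  design <- validate_channel_design(design)
  cfg <- list(
    thresholds = lapply(unclass(thresholds), function(x) {
      if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
    }),
    design = stats::setNames(
      purrr::map2(design$region, design$genotype,
                  function(r, g) list(region = r, genotype = g)),
      design$channel
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
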