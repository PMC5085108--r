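#' @importFrom rlang .data
NULL

psm_meta_cols <- function() {
  c("peptide_sequence", "modifications", "protein_accession", "is_unique",
    "charge", "mascot_score", "sequest_xcorr", "sequest_dcn",
    "percolator_q", "rank", "missed_cleavages", "replicate_id")
}

#' Parse a modifications string
#'
#' Modifications are stored as a compact string `"pos:type;pos:type"`,
#' e.g. `"4:phospho;9:deamidation"`; positions are 1-based indices into
#' the peptide sequence. An empty string means no variable modification.
#'
#' @param x Character vector of modification strings.
#' @return A list of tibbles with columns `position`, `type`.
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(position = integer(), type = character()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      type = vapply(parts, `[`, "", 2L)
    )
  })
}

#' Canonicalize a modifications string
#'
#' Sorts the `pos:type` entries by position then type so that equal
#' modification sets compare equal as strings.
#'
#' @param x Character vector of modification strings.
#' @return Character vector of canonical modification strings.
#' @export
canonical_modifications <- function(x) {
  vapply(parse_modifications(x), function(m) {
    if (nrow(m) == 0) return("")
    m <- m[order(m$position, m$type), ]
    paste(paste0(m$position, ":", m$type), collapse = ";")
  }, "")
}

mod_types <- function() c("phospho", "deamidation", "carbamidomethyl", "itraq8plex")

validate_psm_table <- function(psms) {
  need <- c(psm_meta_cols(), plex_channels())
  miss <- setdiff(need, names(psms))
  if (length(miss)) {
    stop("PSM table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  mods <- parse_modifications(psms$modifications)
  bad_pos <- which(vapply(seq_along(mods), function(i) {
    any(mods[[i]]$position < 1 |
          mods[[i]]$position > nchar(psms$peptide_sequence[i]))
  }, logical(1)))
  if (length(bad_pos)) {
    stop("modification position outside peptide for row(s): ",
         paste(utils::head(bad_pos, 5), collapse = ", "))
  }
  bad_type <- which(vapply(mods, function(m) {
    nrow(m) > 0 && !all(m$type %in% mod_types())
  }, logical(1)))
  if (length(bad_type)) {
    stop("unknown modification type in row(s): ",
         paste(utils::head(bad_type, 5), collapse = ", "))
  }
  invisible(psms)
}

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches, one row per
#' PSM, as exported by a database-search platform: peptide sequence,
#' variable modifications, protein accession, uniqueness flag, charge,
#' search-engine scores (Mascot ion score, Sequest Xcorr and delta-Cn,
#' percolator q-value), rank, missed cleavages, replicate id, and one
#' raw (linear-scale) reporter-intensity column per channel, named by
#' the channel label (113, 114, ..., 119, 121).
#'
#' Empty or `NA` intensity cells become missing values (never zeros);
#' a warning reports how many. Non-numeric intensity text is a row-level
#' error reported with line numbers.
#'
#' @param path Path to a tab-separated UTF-8 file with a header.
#' @param design Optional channel design; validated against the intensity
#'   columns present.
#' @return A tibble with the PSM columns and the eight channel columns.
#' @export
read_psm_table <- function(path, design = default_channel_design()) {
  validate_channel_design(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  need <- c(psm_meta_cols(), plex_channels())
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("PSM table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- function(col, integerish = FALSE) {
    x <- raw[[col]]
    x[x %in% c("", "NA", "NaN")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data line(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (integerish) as.integer(out) else out
  }
  n_na_before <- sum(raw[plex_channels()] %in% c("", "NA"))
  psms <- tibble::tibble(
    peptide_sequence = toupper(raw$peptide_sequence),
    modifications = canonical_modifications(raw$modifications),
    protein_accession = raw$protein_accession,
    is_unique = as.logical(raw$is_unique),
    charge = num("charge", TRUE),
    mascot_score = num("mascot_score"),
    sequest_xcorr = num("sequest_xcorr"),
    sequest_dcn = num("sequest_dcn"),
    percolator_q = num("percolator_q"),
    rank = num("rank", TRUE),
    missed_cleavages = num("missed_cleavages", TRUE)
  )
  for (ch in plex_channels()) {
    x <- raw[[ch]]
    x[x %in% c("", "NA")] <- NA
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      stop("non-numeric intensity in channel ", ch, " at data line(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    psms[[ch]] <- val
  }
  psms$replicate_id <- num("replicate_id", TRUE)
  psms <- psms[, c(psm_meta_cols(), plex_channels())]
  n_missing <- sum(is.na(as.matrix(psms[plex_channels()])))
  if (n_missing > 0) {
    warning(n_missing, " missing reporter intensit",
            if (n_missing == 1) "y" else "ies", " in ", basename(path))
  }
  validate_psm_table(psms)
  psms
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; missing intensities are written as
#' empty cells.
#'
#' @param psms A PSM tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  readr::write_tsv(psms[, c(psm_meta_cols(), plex_channels())], path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' Read a protein sequence database from FASTA
#'
#' The accession is the first whitespace-delimited token of the header;
#' UniProt-style `sp|ACC|NAME` / `tr|ACC|NAME` tokens are additionally
#' split on `|`, taking the accession field. Duplicate accessions,
#' empty files, and sequences with characters outside the 20 standard
#' residues (plus X) are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: accession -> amino-acid sequence.
#' @export
read_protein_fasta <- function(path) {
  # read as raw strings first so residues outside the amino-acid
  # alphabet are reported per accession instead of silently dropped
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("FASTA file ", path, " contains no sequences")
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  bar <- grepl("^(sp|tr)\\|", acc)
  acc[bar] <- vapply(strsplit(acc[bar], "|", fixed = TRUE), `[`, "", 2L)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  db <- stats::setNames(toupper(as.character(seqs)), acc)
  if (any(!nzchar(db))) {
    stop("empty sequence for accession(s): ",
         paste(acc[!nzchar(db)], collapse = ", "))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", db)
  if (any(bad)) {
    stop("illegal residue character(s) in accession(s): ",
         paste(acc[bad], collapse = ", "))
  }
  db
}

#' Write a protein sequence database to FASTA
#'
#' @param db Named character vector: accession -> sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(db, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(db), path, width = 60)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' The file is tab-separated with targets in rows and samples in
#' columns; the first column (`target`) names the assay and the
#' remaining column headers encode the sample as `GENOTYPE_REPLICATE`
#' (e.g. `WT_1`, `AD_3`). "Undetermined" (any capitalisation) and empty
#' wells become missing values.
#'
#' @param path Path to a tab-separated file.
#' @return A long tibble with columns `target`, `sample`, `genotype`,
#'   `replicate`, `ct`.
#' @export
read_ct_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (names(raw)[1] != "target") stop("first column must be named 'target'")
  if (anyDuplicated(raw$target)) {
    stop("duplicate target name(s): ",
         paste(unique(raw$target[duplicated(raw$target)]), collapse = ", "))
  }
  samples <- names(raw)[-1]
  if (!all(grepl("^(WT|AD)_[0-9]+$", samples))) {
    stop("sample columns must be named GENOTYPE_REPLICATE, e.g. WT_1")
  }
  long <- tidyr::pivot_longer(raw, -"target", names_to = "sample",
                              values_to = "ct_raw")
  und <- !is.na(long$ct_raw) & (tolower(long$ct_raw) %in%
                                  c("undetermined", "na", ""))
  long$ct_raw[und] <- NA
  ct <- suppressWarnings(as.numeric(long$ct_raw))
  bad <- which(!is.na(long$ct_raw) & is.na(ct))
  if (length(bad)) {
    stop("non-numeric Ct value(s), e.g. '", long$ct_raw[bad[1]], "'")
  }
  if (any(ct < 0 | ct > 45, na.rm = TRUE)) {
    stop("Ct values outside plausible range 0-45")
  }
  dplyr::transmute(
    long,
    target = .data$target,
    sample = .data$sample,
    genotype = sub("_.*$", "", .data$sample),
    replicate = as.integer(sub("^.*_", "", .data$sample)),
    ct = ct
  )
}

#' Write a qPCR Ct table
#'
#' Inverse of [read_ct_table()]: pivots the long form back to a
#' target x sample grid. Missing wells are written as "Undetermined".
#'
#' @param ct A long Ct tibble as returned by [read_ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(ct, "target", "sample", "ct"),
    names_from = "sample", values_from = "ct"
  )
  wide <- dplyr::mutate(wide, dplyr::across(
    -"target", ~ ifelse(is.na(.x), "Undetermined", format(.x, digits = 15))
  ))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
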