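centered_rows <- function(...) {
  mat <- make_centered_matrix(list(...))
  mat
}

test_that("PTM rollup keeps one-hit-wonders and averages group members", {
  solo <- centered_rows(
    list(peptide_sequence = "AANSTPEPK", modifications = "3:deamidation",
         values = seq(-0.35, 0.35, 0.1))
  )
  out <- rollup_ptm(solo)
  expect_equal(nrow(out), 1)
  expect_equal(unname(unlist(out[, plex_channels()])),
               unname(unlist(solo[, plex_channels()])))
  expect_equal(out$n_peptides, 1)

  pair <- centered_rows(
    list(peptide_sequence = "AASPEPK", modifications = "3:phospho",
         values = rep(0.2, 8)),
    list(peptide_sequence = "AASPEPTIDEK", modifications = "3:phospho",
         values = rep(0.4, 8))
  )
  grouping <- tibble::tibble(feature_id = pair$feature_id,
                             group_id = "site_group")
  out <- rollup_ptm(pair, grouping)
  expect_equal(unname(unlist(out[, plex_channels()])), rep(0.3, 8))
})

test_that("rollups equal a brute-force per-group mean oracle", {
  set.seed(42)
  for (iter in 1:20) {
    n <- sample(4:12, 1)
    rows <- purrr::map(seq_len(n), function(i) {
      list(peptide_sequence = paste0(strrep("A", i), "SPEPK"),
           modifications = "3:phospho",
           values = round(stats::rnorm(8), 3))
    })
    mat <- make_centered_matrix(rows)
    groups <- tibble::tibble(
      feature_id = mat$feature_id,
      group_id = paste0("g", sample(1:3, n, replace = TRUE))
    )
    out <- rollup_ptm(mat, groups)
    for (g in unique(groups$group_id)) {
      members <- mat[mat$feature_id %in%
                       groups$feature_id[groups$group_id == g], ]
      oracle <- colMeans(as.matrix(members[, plex_channels()]))
      expect_equal(unname(unlist(out[out$feature_id == g, plex_channels()])),
                   unname(oracle))
    }
  }
})

test_that("protein rollup needs two unique peptides, single hits go to the side table", {
  mat <- centered_rows(
    list(peptide_sequence = "AAAPEPK", protein_accession = "P1",
         values = rep(0, 8)),
    list(peptide_sequence = "CCCPEPK", protein_accession = "P1",
         values = rep(0.3, 8)),
    list(peptide_sequence = "DDDPEPK", protein_accession = "P1",
         values = rep(0.6, 8)),
    list(peptide_sequence = "EEEPEPK", protein_accession = "P2",
         values = rep(0.5, 8)),
    # modified peptides never contribute to protein rollup
    list(peptide_sequence = "FFSPEPK", protein_accession = "P2",
         modifications = "3:phospho", values = rep(9, 8))
  )
  out <- rollup_protein(mat)
  expect_identical(out$proteins$protein_accession, "P1")
  expect_equal(unname(unlist(out$proteins[, plex_channels()])), rep(0.3, 8))
  expect_identical(out$single_peptide$protein_accession, "P2")
  expect_equal(unname(unlist(out$single_peptide[, plex_channels()])),
               rep(0.5, 8))
})

test_that("proteoform-ambiguous evidence is removed before rollup", {
  mat <- centered_rows(
    list(peptide_sequence = "AAAPEPK", protein_accession = "P1",
         values = rep(0, 8)),
    list(peptide_sequence = "CCCPEPK", protein_accession = "P1",
         values = rep(1, 8)),
    # same peptide set under an isoform suffix: redundant proteoform
    list(peptide_sequence = "AAAPEPK", protein_accession = "P1-2",
         values = rep(0, 8)),
    list(peptide_sequence = "CCCPEPK", protein_accession = "P1-2",
         values = rep(1, 8)),
    # non-unique peptide: excluded entirely
    list(peptide_sequence = "GGGPEPK", protein_accession = "P3",
         is_unique = FALSE, values = rep(5, 8))
  )
  out <- suppressMessages(rollup_protein(mat))
  expect_identical(out$proteins$protein_accession, "P1")
  expect_false("P3" %in% c(out$proteins$protein_accession,
                           out$single_peptide$protein_accession))
})

test_that("region ratios match direct recomputation and handle the null case", {
  vals1 <- c(0, 1, 0.5, 0.5, 0, 0, 0, 0)   # AD - WT = 1 in hippocampus
  rows <- purrr::map(1:3, function(r) {
    list(peptide_sequence = "AAAPEPK", replicate_id = r, values = vals1)
  })
  mat <- make_centered_matrix(rows)
  rr <- compute_ratios(mat, regions = "hippocampus")
  expect_equal(unname(unlist(rr[, c("ratio_rep1", "ratio_rep2",
                                    "ratio_rep3")])), c(2, 2, 2))
  expect_equal(rr$mean_ratio, 2)
  expect_equal(rr$rel_sd, 0)
  expect_equal(rr$n_observed, 3)
  nc <- compute_ratios(mat, regions = "neocortex")
  expect_equal(nc$mean_ratio, 1)

  set.seed(9)
  rows <- purrr::map(1:3, function(r) {
    list(peptide_sequence = "CCCPEPK", replicate_id = r,
         values = stats::rnorm(8))
  })
  mat <- make_centered_matrix(rows)
  for (rg in plex_regions()) {
    d <- default_channel_design()
    wt <- d$channel[d$region == rg & d$genotype == "WT"]
    ad <- d$channel[d$region == rg & d$genotype == "AD"]
    oracle <- 2^(mat[[ad]] - mat[[wt]])
    rr <- compute_ratios(mat, regions = rg)
    expect_equal(unname(unlist(rr[, paste0("ratio_rep", 1:3)])), oracle)
    expect_equal(rr$mean_ratio, mean(oracle))
    expect_equal(rr$rel_sd, sd(oracle) / mean(oracle))
  }
})

test_that("a replicate counts as observed only when both channels are present", {
  rows <- list(
    list(peptide_sequence = "AAAPEPK", replicate_id = 1L,
         values = c(0, 1, rep(0, 6))),
    list(peptide_sequence = "AAAPEPK", replicate_id = 2L,
         values = c(NA, 1, 0, 0, 0, NA, 0, 0)),     # WT missing
    list(peptide_sequence = "AAAPEPK", replicate_id = 3L,
         values = c(0, NA, 0, 0, 0, 0, 0, NA))      # AD missing
  )
  rr <- compute_ratios(make_centered_matrix(rows), regions = "hippocampus")
  expect_equal(rr$n_observed, 1)
  expect_true(is.na(rr$rel_sd))
})

test_that("PTM ratios normalize elementwise by protein ratios", {
  ptm <- make_ratios(list(c(2.6, 2.6, 2.6)), feature_ids = "pep1")
  ptm$protein_accession <- "P1"
  prot <- make_ratios(list(c(2.0, 2.0, 2.0)), feature_ids = "P1")
  out <- normalize_ptm_ratios(ptm, prot)
  expect_equal(unname(unlist(out[, paste0("ratio_rep", 1:3)])),
               rep(1.3, 3))
  expect_equal(out$mean_ratio, 1.3)
  expect_true(out$normalized)
  expect_equal(out$n_normalized, 3)

  # protein ratio of exactly 1 leaves the record unchanged
  unity <- make_ratios(list(rep(1, 3)), feature_ids = "P1")
  out2 <- normalize_ptm_ratios(ptm, unity)
  expect_equal(out2$mean_ratio, 2.6)

  # replicate without protein quantification stays un-normalized
  gap <- make_ratios(list(c(2, NA, 2)), feature_ids = "P1")
  out3 <- normalize_ptm_ratios(ptm, gap)
  expect_equal(unname(unlist(out3[, paste0("ratio_rep", 1:3)])),
               c(1.3, 2.6, 1.3))
  expect_equal(out3$n_normalized, 2)

  # random elementwise oracle
  set.seed(3)
  for (i in 1:20) {
    pr <- stats::runif(3, 0.5, 2)
    pp <- stats::runif(3, 0.5, 2)
    ptm_i <- make_ratios(list(pp), feature_ids = "x")
    ptm_i$protein_accession <- "P9"
    prot_i <- make_ratios(list(pr), feature_ids = "P9")
    out_i <- normalize_ptm_ratios(ptm_i, prot_i)
    expect_equal(unname(unlist(out_i[, paste0("ratio_rep", 1:3)])), pp / pr)
  }
})

test_that("sequon check implements N-X-S/T/C with X != P", {
  db <- c(P1 = "MKNGSAA", P2 = "MKNPTAA", P3 = "MKAAAN", P4 = "MKAANG",
          P5 = "MKDGTAA", P6 = "MKNGXAA")
  expect_true(check_sequon(db, "P1", 3))       # N-G-S
  expect_false(check_sequon(db, "P2", 3))      # X = P
  expect_false(check_sequon(db, "P3", 6))      # N at last residue
  expect_false(check_sequon(db, "P4", 5))      # N at penultimate residue
  expect_true(check_sequon(db, "P5", 3))       # deamidated N -> D accepted
  expect_false(check_sequon(db, "P6", 3))      # +2 not in S/T/C
  expect_error(check_sequon(db, "P1", 99), "out of range")
  expect_error(check_sequon(db, "P1", 1), "not N")
  expect_error(check_sequon(db, "NOPE", 1), "unknown accession")
})

test_that("deregulation calls follow presence, SD and ratio criteria", {
  t <- default_thresholds()
  calls <- call_deregulation(
    make_ratios(list(c(1.35, 1.32, 1.40),
                     c(1.0, 1.0, 1.0),
                     c(0.77, 0.77, 0.77),
                     c(3.0, 0.4, 1.1),       # huge spread: rel_sd fails
                     c(1.5, NA, NA))),       # presence fails
    t, n_replicates = 3)
  expect_equal(as.character(calls$direction),
               c("up", "none", "down", "none", "none"))
  expect_true(calls$presence_ok[1] && calls$sd_ok[1])
  expect_false(calls$sd_ok[4])
  expect_false(calls$presence_ok[5])

  # deglyco features additionally need the sequon flag
  glyco <- make_ratios(list(c(1.5, 1.5, 1.5)))
  glyco$sequon_ok <- FALSE
  expect_equal(as.character(call_deregulation(glyco, t, 3)$direction),
               "none")
  glyco$sequon_ok <- TRUE
  expect_equal(as.character(call_deregulation(glyco, t, 3)$direction), "up")

  # proteins must keep their two-unique-peptide identification
  prot <- make_ratios(list(c(1.5, 1.5, 1.5)))
  prot$min_peptides <- 1L
  expect_equal(as.character(call_deregulation(prot, t, 3)$direction), "none")
})

test_that("increasing AD channel values never flips a call from up to down", {
  set.seed(11)
  rank_dir <- c(up = 2, none = 1, down = 0)
  for (i in 1:50) {
    base <- stats::runif(3, 0.4, 2.5)
    r0 <- call_deregulation(make_ratios(list(base)), n_replicates = 3)
    bumped <- base * stats::runif(1, 1, 3)  # raise every AD value
    r1 <- call_deregulation(make_ratios(list(bumped)), n_replicates = 3)
    d0 <- as.character(r0$direction)
    d1 <- as.character(r1$direction)
    expect_false(d0 == "up" && d1 == "down")
  }
})

test_that("calls are invariant to replicate mean-centering", {
  sim <- simulate_psm_tables(simulation_params(n_proteins = 12, seed = 8))
  norm <- sim$psms |> filter_psms() |> psm_to_log2() |> median_normalize()
  cen <- center_features(norm)
  # ratios from centered data equal ratios recomputed from the
  # un-centered normalized values (centering cancels in AD - WT)
  uncentered <- norm[paste(norm$feature_id, norm$replicate_id) %in%
                       paste(cen$feature_id, cen$replicate_id), ]
  d <- default_channel_design()
  for (rg in c("hippocampus", "brainstem")) {
    wt <- d$channel[d$region == rg & d$genotype == "WT"]
    ad <- d$channel[d$region == rg & d$genotype == "AD"]
    rr <- compute_ratios(cen, regions = rg)
    oracle <- tibble::tibble(
      feature_id = uncentered$feature_id,
      replicate_id = uncentered$replicate_id,
      ratio = 2^(uncentered[[ad]] - uncentered[[wt]])
    )
    long <- tidyr::pivot_longer(rr, dplyr::starts_with("ratio_rep"),
                                names_to = "rep", values_to = "ratio") |>
      dplyr::mutate(replicate_id = as.integer(sub("ratio_rep", "", rep)))
    joined <- dplyr::inner_join(long, oracle,
                                by = c("feature_id", "replicate_id"))
    ok <- !is.na(joined$ratio.x) & !is.na(joined$ratio.y)
    expect_gt(sum(ok), 0)
    expect_equal(joined$ratio.x[ok], joined$ratio.y[ok], tolerance = 1e-10)
  }
})

test_that("PTM features are classified and mapped onto protein coordinates", {
  db <- c(PX = "MKAANGSAAKSSSK")
  mat <- centered_rows(
    list(peptide_sequence = "AANGSAAK", protein_accession = "PX",
         modifications = "3:deamidation", values = rep(0, 8)),
    list(peptide_sequence = "SSSK", protein_accession = "PX",
         modifications = "1:phospho", values = rep(0, 8))
  )
  feats <- ptm_features(mat, db)
  glyco <- feats[feats$feature_kind == "deglyco", ]
  phos <- feats[feats$feature_kind == "phospho", ]
  expect_equal(glyco$site_positions[[1]], 5L)   # N of NGS in protein coords
  expect_true(check_sequon(db, "PX", glyco$site_positions[[1]]))
  expect_equal(phos$site_positions[[1]], 11L)
})
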