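test_that("PSM filter applies the score cut-offs with correct boundaries", {
  t <- default_thresholds()
  boundary <- make_psm(mascot_score = 22, percolator_q = 0.01,
                       sequest_dcn = 0.1, charge = 2L, sequest_xcorr = 2.01)
  expect_equal(nrow(filter_psms(boundary, t)), 1)  # >= bounds inclusive

  # Xcorr bound is strict: exactly 2.0 at charge +2 is rejected
  expect_equal(nrow(filter_psms(make_psm(charge = 2L, sequest_xcorr = 2), t)), 0)
  expect_equal(nrow(filter_psms(make_psm(missed_cleavages = 2L), t)), 0)
  expect_equal(nrow(filter_psms(make_psm(rank = 2L), t)), 0)
  expect_equal(nrow(filter_psms(make_psm(percolator_q = 0.011), t)), 0)
  expect_equal(nrow(filter_psms(make_psm(mascot_score = 21.9), t)), 0)
  expect_equal(nrow(filter_psms(make_psm(sequest_dcn = 0.09), t)), 0)

  # charges above +4 use the +4 bound
  expect_equal(nrow(filter_psms(make_psm(charge = 6L, sequest_xcorr = 2.51), t)), 1)
  expect_equal(nrow(filter_psms(make_psm(charge = 6L, sequest_xcorr = 2.4), t)), 0)

  # non-positive charge is rejected with a diagnostic
  expect_warning(out <- filter_psms(make_psm(charge = 0L), t), "charge")
  expect_equal(nrow(out), 0)

  # a missing score fails its criterion
  expect_equal(nrow(filter_psms(make_psm(mascot_score = NA_real_), t)), 0)
})

test_that("PSM filter is idempotent and order-preserving", {
  sim <- simulate_psm_tables(simulation_params(n_proteins = 15, seed = 4))
  once <- filter_psms(sim$psms)
  expect_identical(filter_psms(once), once)
  key <- function(df) paste(df$peptide_sequence, df$modifications,
                            df$replicate_id, df$mascot_score)
  expect_false(is.unsorted(match(key(once), key(sim$psms))))
})

test_that("log2 conversion matches an elementwise oracle and handles zeros", {
  psms <- dplyr::bind_rows(
    make_psm(intensities = rep(8, 8)),
    make_psm(peptide_sequence = "OTHERPEPK", intensities = rep(1, 8))
  )
  mat <- psm_to_log2(psms)
  expect_equal(unname(unlist(mat[mat$peptide_sequence == "ELVISLIVESK",
                                 plex_channels()])), rep(3, 8))
  expect_equal(unname(unlist(mat[mat$peptide_sequence == "OTHERPEPK",
                                 plex_channels()])), rep(0, 8))
  expect_identical(scale_state(mat), "raw_log2")

  set.seed(1)
  vals <- matrix(stats::runif(40, 10, 1e6), 5)
  psms <- purrr::map_dfr(1:5, function(i) {
    make_psm(peptide_sequence = paste0(strrep("A", i), "PEPTIDEK"),
             intensities = vals[i, ])
  })
  mat <- dplyr::arrange(psm_to_log2(psms), nchar(peptide_sequence))
  expect_equal(unname(as.matrix(mat[, plex_channels()])), log2(vals))

  expect_warning(z <- psm_to_log2(make_psm(intensities = c(0, rep(10, 7)))),
                 "non-positive")
  expect_true(is.na(z$`113`))
})

test_that("PSMs of one feature aggregate by the median intensity per channel", {
  psms <- dplyr::bind_rows(
    make_psm(intensities = rep(100, 8)),
    make_psm(intensities = rep(200, 8)),
    make_psm(intensities = rep(1000, 8))  # outlier spectrum
  )
  mat <- psm_to_log2(psms)
  expect_equal(nrow(mat), 1)
  expect_equal(unname(unlist(mat[, plex_channels()])), rep(log2(200), 8))
})

test_that("median normalization zeroes every channel median and is idempotent", {
  psms <- purrr::map_dfr(1:9, function(i) {
    make_psm(peptide_sequence = paste0(strrep("G", i), "PEPK"),
             intensities = 2^stats::runif(8, 4, 12))
  })
  m1 <- median_normalize(psm_to_log2(psms))
  meds <- apply(as.matrix(m1[, plex_channels()]), 2, median)
  expect_equal(unname(meds), rep(0, 8), tolerance = 1e-9)
  expect_identical(scale_state(m1), "median_normalized")
  m2 <- median_normalize(m1)
  expect_equal(as.matrix(m2[, plex_channels()]),
               as.matrix(m1[, plex_channels()]))

  const <- median_normalize(psm_to_log2(make_psm(intensities = rep(32, 8))))
  expect_equal(unname(unlist(const[, plex_channels()])), rep(0, 8))

  three <- purrr::map_dfr(1:3, function(i) {
    make_psm(peptide_sequence = paste0(strrep("S", i), "PEPK"),
             intensities = rep(2^i, 8))
  })
  mn <- median_normalize(psm_to_log2(three))
  expect_equal(sort(mn$`113`), c(-1, 0, 1))
})

test_that("feature centering zeroes row means and preserves channel differences", {
  rows <- list(list(peptide_sequence = "AAAK", values = as.numeric(1:8)),
               list(peptide_sequence = "CCCK", values = c(NA, 2, 4, NA, 6, 8, 10, 12)),
               list(peptide_sequence = "DDDK", values = c(-2, 2, rep(NA, 6))))
  mat <- make_centered_matrix(rows)   # raw values, fix state by hand
  attr(mat, "scale_state") <- "median_normalized"
  cen <- center_features(mat)
  vals <- as.matrix(cen[, plex_channels()])
  expect_equal(unname(rowMeans(vals, na.rm = TRUE)), rep(0, 3))
  expect_equal(unname(vals[1, ]), seq(-3.5, 3.5, 1))
  # within-row differences unchanged
  before <- as.matrix(mat[, plex_channels()])
  expect_equal(vals[2, 3] - vals[2, 2], before[2, 3] - before[2, 2])
  # already-centered input is unchanged
  attr(cen, "scale_state") <- "median_normalized"
  expect_equal(as.matrix(center_features(cen)[, plex_channels()]), vals)
  # rows with < 2 observed channels are dropped with a warning
  one <- make_centered_matrix(list(list(values = c(1, rep(NA, 7)))))
  attr(one, "scale_state") <- "median_normalized"
  expect_warning(out <- center_features(one), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("scale state only moves forward through the pipeline", {
  mat <- psm_to_log2(make_psm())
  expect_error(center_features(mat), "median_normalized")
  cen <- center_features(median_normalize(mat))
  expect_identical(scale_state(cen), "mean_centered")
  expect_error(median_normalize(cen), "raw_log2")
})

test_that("PCA matches a dense eigendecomposition oracle up to sign", {
  set.seed(7)
  rows <- purrr::map(1:6, function(i) {
    list(peptide_sequence = paste0(strrep("L", i), "PEPK"),
         values = stats::rnorm(8))
  })
  mat <- make_centered_matrix(rows)
  pca <- run_pca(mat)
  x <- t(as.matrix(mat[, plex_channels()]))      # 8 samples x 6 features
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc))
  scores_oracle <- xc %*% eig$vectors
  pcs <- paste0("PC", 1:6)
  got <- as.matrix(pca$scores[, pcs])
  expect_equal(abs(unname(got)), abs(unname(scores_oracle[, 1:6])),
               tolerance = 1e-8)
  expect_equal(pca$explained_variance, eig$values / sum(eig$values),
               tolerance = 1e-8)
})

test_that("PCA gives identical samples identical scores and valid variances", {
  rows <- purrr::map(1:5, function(i) {
    v <- stats::rnorm(8)
    v[2] <- v[1]   # channels 113 and 114 identical
    list(peptide_sequence = paste0(strrep("V", i), "PEPK"), values = v)
  })
  pca <- run_pca(make_centered_matrix(rows))
  s113 <- as.numeric(pca$scores[pca$scores$channel == "113",
                                paste0("PC", 1:5)])
  s114 <- as.numeric(pca$scores[pca$scores$channel == "114",
                                paste0("PC", 1:5)])
  expect_equal(s113, s114, tolerance = 1e-10)
  ev <- pca$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)
  expect_error(run_pca(make_centered_matrix(rows[1])), "fewer than 2")
})

test_that("tidy, glance and autoplot work on a PCA result", {
  sim <- simulate_psm_tables(simulation_params(n_proteins = 10, seed = 5))
  mat <- sim$psms |> filter_psms() |> psm_to_log2() |>
    median_normalize() |> center_features()
  pca <- suppressMessages(run_pca(mat))
  td <- tidy(pca)
  expect_true(all(c("component", "score", "genotype") %in% names(td)))
  expect_equal(nrow(td), 24 * length(pca$explained_variance))
  gl <- glance(pca)
  expect_equal(gl$n_samples, 24)
  expect_s3_class(autoplot(pca), "ggplot")
})
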