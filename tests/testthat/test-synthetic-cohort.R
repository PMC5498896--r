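test_that("karyotype simulation honours degenerate probabilities and seeds", {
  cfg <- cohort_config(n_embryos = 10, p_male = 1, p_y_loss_in_males = 0,
                       p_wga_failure = 0, seed = 42)
  k <- simulate_karyotypes(cfg)
  expect_equal(nrow(k), 10)
  expect_true(all(k$sex == "male"))
  expect_true(all(k$y_copies == 1))

  cfg2 <- cohort_config(n_embryos = 500, seed = 7)
  expect_identical(simulate_karyotypes(cfg2), simulate_karyotypes(cfg2))
  expect_false(identical(simulate_karyotypes(cfg2),
                         simulate_karyotypes(cfg2, seed = 8)))

  expect_error(cohort_config(p_male = 1.2), "probability")
  expect_error(cohort_config(p_trisomy18 = 0.6, p_trisomy21 = 0.6), "exceed 1")
})

test_that("male prevalence matches the configured 146/328 at large n", {
  p <- 146 / 328
  k <- simulate_karyotypes(cohort_config(n_embryos = 100000, p_male = p,
                                         seed = 10))
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(mean(k$sex == "male") - p), 3 * se)
})

test_that("locus detections follow presence exactly when error-free", {
  cfg <- cohort_config(n_embryos = 300, p_wga_failure = 0, seed = 2)
  k <- simulate_karyotypes(cfg)
  em0 <- error_model(ado = c(SRY = 0, DYS14 = 0, AMELY = 0),
                     fa = c(SRY = 0, DYS14 = 0, AMELY = 0), gapdh_detect = 1)
  d <- simulate_locus_detections(k, em0, seed = 3)
  expect_identical(d$detected, d$present)

  # fa = 1: every female positive for the locus
  em1 <- error_model(ado = c(SRY = 0), fa = c(SRY = 1), gapdh_detect = 1)
  kf <- simulate_karyotypes(cohort_config(n_embryos = 50, p_male = 0,
                                          p_y_fragment_in_females = 0,
                                          p_wga_failure = 0, seed = 4))
  df <- simulate_locus_detections(kf, em1, seed = 5)
  expect_true(all(df$detected[df$locus == "SRY"]))

  expect_error(locus_present(k, "NOPE"), "unknown locus")
})

test_that("SRY drop-out rate in males recovers the generating 13.5%", {
  k <- simulate_karyotypes(cohort_config(n_embryos = 10000, p_male = 1,
                                         p_y_loss_in_males = 0,
                                         p_wga_failure = 0, seed = 11))
  d <- simulate_locus_detections(k, error_model(gapdh_detect = 1), seed = 12)
  sry <- d[d$locus == "SRY", ]
  miss <- mean(!sry$detected)
  se <- sqrt(0.135 * 0.865 / 10000)
  expect_lt(abs(miss - 0.135), 3 * se)
})

test_that("Ct panel reproduces the ideal-WGA shift and standard-curve slope", {
  k <- simulate_karyotypes(cohort_config(n_embryos = 4, p_male = 0.5, seed = 1))
  k$chr21_copies <- c(2L, 3L, 2L, 3L)
  k$chr18_copies <- 2L
  ideal <- ct_model_params(gamma_mean = c(TTC3 = 1, RPL17 = 1),
                           gamma_sd = c(TTC3 = 0, RPL17 = 0),
                           sigma_delta = c(TTC3 = 0, RPL17 = 0),
                           sigma_sample = 0, sigma_tech = 0)
  ct <- simulate_ct_panel(k, ideal, seed = 1)
  d2 <- delta_ct(ct, k$embryo_id[1], "TTC3")
  d3 <- delta_ct(ct, k$embryo_id[2], "TTC3")
  expect_equal(d3 - d2, -log2(3 / 2), tolerance = 1e-12)

  # three collinear points force the least-squares slope exactly
  qc <- standard_curve_qc(ct, k$embryo_id[1], "HSDB")
  expect_equal(qc$slope, ideal$standard_slope, tolerance = 1e-9)
  expect_true(qc$pass)

  # Ct strictly decreasing with mass when technical noise is off
  one <- ct[ct$embryo_id == k$embryo_id[1] & ct$gene == "TTC3", ]
  one <- one[order(one$input_ng), ]
  expect_true(all(diff(one$ct) < 0))

  expect_error(simulate_ct_panel(k, ideal, masses = c(-1, 15)), "positive")
  expect_error(simulate_ct_panel(k, ideal, masses = c(3.75, 7.5)), "15 ng")
})

test_that("delta-Ct cancels the sample-level WGA offset", {
  k <- simulate_karyotypes(cohort_config(n_embryos = 50, seed = 9))
  pars <- ct_model_params(gamma_sd = c(TTC3 = 0, RPL17 = 0),
                          sigma_delta = c(TTC3 = 0, RPL17 = 0),
                          sigma_sample = 5, sigma_tech = 0)
  ct <- simulate_ct_panel(k, pars, seed = 10)
  dct <- vapply(k$embryo_id, function(id) delta_ct(ct, id, "RPL17"), numeric(1))
  expected <- pars$mu[["RPL17"]] -
    pars$gamma_mean[["RPL17"]] * log2(k$chr18_copies / 2)
  expect_equal(unname(dct), unname(expected), tolerance = 1e-9)
})

test_that("calibrated defaults reproduce the trisomy-panel group means", {
  k <- simulate_karyotypes(cohort_config(n_embryos = 10000, seed = 21))
  ct <- simulate_ct_panel(k, ct_model_params(), seed = 22)
  at15 <- function(g) {
    rows <- ct[ct$gene == g & ct$input_ng == 15, ]
    rows$ct[match(k$embryo_id, rows$embryo_id)]
  }
  dct <- at15("TTC3") - at15("HSDB")
  normal <- k$chr21_copies == 2
  t21 <- k$chr21_copies == 3
  expect_lt(abs(mean(dct[normal]) - 4.77), 3 * 0.56 / sqrt(sum(normal)))
  expect_lt(abs(mean(dct[t21]) - 3.39), 3 * 0.99 / sqrt(sum(t21)))
  # gamma dispersion widens the trisomic group to the reported spread
  expect_equal(stats::sd(dct[t21]), 0.99, tolerance = 0.05)
})

test_that("melt traces have the analytic baseline and peak structure", {
  pars <- melt_model_params(noise_sd = 0)
  flat <- simulate_melt_curve(character(), pars)
  d <- negative_derivative(flat$temperature_c, flat$fluorescence)
  expect_equal(d, rep(-pars$baseline_slope, length(d)), tolerance = 1e-9)

  one <- simulate_melt_curve("SRY", pars)
  d1 <- negative_derivative(one$temperature_c, one$fluorescence)
  expect_lte(abs(one$temperature_c[which.max(d1)] - pars$tm[["SRY"]]), 0.2)

  # two transitions 4 degrees apart with width 0.8 resolve into two peaks
  pars2 <- melt_model_params(tm = c(A = 80, B = 84), noise_sd = 0)
  two <- simulate_melt_curve(c("A", "B"), pars2)
  d2 <- negative_derivative(two$temperature_c, two$fluorescence)
  pk <- call_peaks(two$temperature_c, d2, min_height = 5)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$tm, c(80, 84), tolerance = 0.21)

  expect_error(simulate_melt_curve("XYZ", pars), "unknown amplicon")
  expect_error(melt_model_params(temperature_grid = numeric()), "ascending")
})

test_that("electropherograms place AMELX/AMELY peaks per the error model", {
  pars <- amel_model_params(size_jitter_sd = 0)
  # error-free female: no peak near 110 bp
  kf <- simulate_karyotypes(cohort_config(n_embryos = 200, p_male = 0,
                                          p_y_fragment_in_females = 0,
                                          p_wga_failure = 0, seed = 31))
  em0 <- error_model(ado = c(AMELY = 0), fa = c(AMELY = 0), gapdh_detect = 1)
  df <- simulate_locus_detections(kf, em0, seed = 32)
  pf <- simulate_electropherograms(kf, df, pars, seed = 33)
  expect_false(any(abs(pf$size_bp - 110) <= 1))
  expect_equal(sum(abs(pf$size_bp - 104) <= 1), 200)

  # detected male: peaks at both expected sizes
  km <- simulate_karyotypes(cohort_config(n_embryos = 10000, p_male = 1,
                                          p_y_loss_in_males = 0,
                                          p_wga_failure = 0, seed = 34))
  dm <- simulate_locus_detections(km, em0, seed = 35)
  pm <- simulate_electropherograms(km, dm, pars, seed = 36)
  ps <- amel_peakset(pm)
  expect_true(all(ps$amelx_height > 0 & ps$amely_height > 0))

  # lognormal median identity for the AMELY height
  med <- stats::median(log(ps$amely_height))
  se_med <- 1.2533 * pars$height_log_sd / sqrt(10000)
  expect_lt(abs(med - pars$height_log_mean), 3 * se_med)
})

test_that("a whole simulated cohort is byte-identical under one seed", {
  cfg <- pipeline_config(cohort = cohort_config(n_embryos = 60, seed = 77))
  a <- simulate_cohort(cfg, melt_curves = TRUE)
  b <- simulate_cohort(cfg, melt_curves = TRUE)
  expect_identical(a, b)
})
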