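test_that("noiseless data give back the generating parameters", {
  fit <- fit_melt_curve(noiseless_profile(550, 10, 0))
  expect_true(fit$valid)
  expect_lt(abs(fit$a - 550) / 550, 1e-4)
  expect_lt(abs(fit$b - 10) / 10, 1e-4)
  expect_lt(fit$plateau, 1e-4)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$tm_c, 55, tolerance = 1e-3)
})

test_that("parameter recovery holds across 100 random noiseless draws", {
  set.seed(5)
  worst <- 0
  for (i in 1:100) {
    b <- runif(1, 8, 13)
    plateau <- runif(1, 0, 0.25)
    tm <- runif(1, 45, 66)
    a <- tm * (b - log(0.5 / (0.5 - plateau)))
    fit <- fit_melt_curve(noiseless_profile(a, b, plateau))
    rel <- max(abs(fit$a - a) / a, abs(fit$b - b) / b,
               abs(fit$plateau - plateau) / max(plateau, 1))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-4)
})

test_that("degenerate profiles are flagged instead of raising", {
  flat <- data.frame(temperature_c = seq(37, 67, length.out = 10),
                     rel_abundance = rep(1, 10))
  fit <- fit_melt_curve(flat)
  expect_false(fit$valid)
  short <- data.frame(temperature_c = c(37, 45, 55, 65),
                      rel_abundance = c(1, .8, .4, .1))
  expect_error(fit_melt_curve(short), class = "tppshift_input_error")
})

test_that("broom-style accessors expose the fit consistently", {
  fit <- fit_melt_curve(noiseless_profile(550, 10, 0.05))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "plateau"))
  gl <- glance(fit)
  expect_true(gl$valid)
  expect_equal(gl$tm_c, fit$tm_c)
  au <- augment(fit)
  expect_equal(au$.resid, au$rel_abundance - au$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("Tm estimates stay within 1 C of truth under realistic noise", {
  sim <- simulate_tpp(sim_config(n_proteins = 200, shift_fraction = 0,
                                 noise_sd = 0.05, n_replicates = 1,
                                 seed = 14L))
  fits <- fit_melt_curves(
    dplyr::filter(sim$profiles, condition == "vehicle"))
  truth <- sim$truth[sim$truth$condition == "vehicle",
                     c("protein_id", "tm_c")]
  names(truth)[2] <- "tm_true"
  joined <- dplyr::inner_join(fits, truth, by = "protein_id")
  err <- abs(joined$tm_c - joined$tm_true)
  expect_gt(mean(!is.na(err)), 0.95)
  expect_lt(median(err, na.rm = TRUE), 1)
})

test_that("quality filter applies the configured thresholds", {
  fits <- tibble::tibble(
    protein_id = c("A", "B", "C", "D"),
    condition = "vehicle", replicate = 1L,
    a = 550, b = 10,
    plateau = c(0.05, 0.05, 0.45, 0.05),
    rss = 0.01,
    r_squared = c(0.99, 0.5, 0.99, 0.9),
    tm_c = c(55, 55, NA, NA),
    valid = TRUE)
  out <- curve_quality_filter(fits)
  expect_equal(out$quality_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(curve_quality_filter(fits, keep = TRUE)), 1)
  ## configurable: loosening r2 re-admits B only if Tm is defined
  out2 <- curve_quality_filter(fits, r2_min = 0.4)
  expect_equal(out2$quality_pass, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("delta Tm is treatment minus vehicle and omits undefined pairs", {
  fits <- tibble::tibble(
    protein_id = rep(c("P1", "P2", "P3"), each = 2),
    condition = rep(c("vehicle", "treatment"), 3),
    replicate = 1L,
    tm_c = c(55, 55, 55, 58, NA, 60))
  dt <- delta_tm(fits)
  expect_equal(dt$protein_id, c("P1", "P2"))
  expect_equal(dt$delta_tm_c, c(0, 3))
})

test_that("injected shifts are recovered by per-replicate delta Tm", {
  sim <- simulate_tpp(sim_config(n_proteins = 120, shift_fraction = 1,
                                 delta_tm_mean = 3, delta_tm_sd = 0.3,
                                 noise_sd = 0.03, seed = 8L))
  fits <- fit_melt_curves(sim$profiles)
  dt <- delta_tm(fits)
  expect_gt(nrow(dt), 100)
  expect_lt(abs(mean(dt$delta_tm_c) - 3), 0.5)
})

test_that("replicate Tm correlation handles exact and degenerate inputs", {
  tm <- c(50, 55, 60, 65)
  fits <- tibble::tibble(
    protein_id = rep(paste0("P", 1:4), 2),
    condition = "vehicle",
    replicate = rep(1:2, each = 4),
    tm_c = c(tm, tm))
  expect_equal(replicate_tm_correlation(fits)$r, 1)
  ## second replicate mirrored around the mean -> perfect anticorrelation
  fits$tm_c[5:8] <- 2 * mean(tm) - tm
  expect_equal(replicate_tm_correlation(fits)$r, -1)
  expect_error(replicate_tm_correlation(fits[c(1, 5), ]),
               class = "tppshift_statistics_error")
})
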