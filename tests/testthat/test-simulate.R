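test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_proteins = 0), "n_proteins",
               class = "tppshift_config_error")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd",
               class = "tppshift_config_error")
  expect_error(sim_config(shift_fraction = 1.5), "shift_fraction",
               class = "tppshift_config_error")
  expect_error(sim_config(temperatures = c(37, 40, 39, 50, 60, 67)),
               "temperatures", class = "tppshift_config_error")
  expect_error(sim_config(plateau_range = c(0, 0.6)), "plateau_range",
               class = "tppshift_config_error")
  expect_length(validate_sim_config(sim_config()), 0)
})

test_that("identical seeds give identical datasets", {
  cfg <- sim_config(n_proteins = 50, shift_fraction = 0.1, seed = 11L)
  s1 <- simulate_tpp(cfg)
  s2 <- simulate_tpp(cfg)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_tpp(sim_config(n_proteins = 50, shift_fraction = 0.1,
                                seed = 12L))
  expect_false(identical(s1$profiles, s3$profiles))
})

test_that("zero noise and no shift give point-for-point identical conditions", {
  sim <- simulate_tpp(sim_config(n_proteins = 10, noise_sd = 0,
                                 shift_fraction = 0, seed = 4L))
  wide <- tidyr::pivot_wider(sim$profiles, names_from = condition,
                             values_from = rel_abundance)
  expect_equal(wide$vehicle, wide$treatment)
})

test_that("noiseless profiles equal the sigmoid model on the grid", {
  sim <- simulate_tpp(sim_config(n_proteins = 8, noise_sd = 0, seed = 2L))
  joined <- dplyr::left_join(
    sim$profiles,
    sim$truth[, c("protein_id", "condition", "a", "b", "plateau")],
    by = c("protein_id", "condition"))
  expect_equal(joined$rel_abundance,
               melt_sigmoid(joined$temperature_c, joined$a, joined$b,
                            joined$plateau))
})

test_that("expected abundance is monotone non-increasing in temperature", {
  sim <- simulate_tpp(sim_config(n_proteins = 40, noise_sd = 0, seed = 9L))
  drops <- sim$profiles |>
    dplyr::group_by(protein_id, condition, replicate) |>
    dplyr::summarise(mono = all(diff(rel_abundance) <= 1e-12),
                     .groups = "drop")
  expect_true(all(drops$mono))
})

test_that("ground truth bookkeeping is exact", {
  sim <- simulate_tpp(sim_config(n_proteins = 200, shift_fraction = 0.3,
                                 seed = 21L))
  tr <- tidyr::pivot_wider(sim$truth, id_cols = c(protein_id, shifter,
                                                  delta_tm_true),
                           names_from = condition, values_from = tm_c)
  non <- tr[!tr$shifter, ]
  expect_equal(non$treatment, non$vehicle)
  sh <- tr[tr$shifter, ]
  expect_gt(nrow(sh), 0)
  expect_equal(sh$treatment - sh$vehicle, sh$delta_tm_true, tolerance = 1e-9)
  ## baseline Tm respects the configured human-proteome-like range
  veh <- sim$truth[sim$truth$condition == "vehicle", ]
  expect_true(all(veh$tm_c >= 45 & veh$tm_c <= 70))
})

test_that("injected shift mean converges to the configured mean", {
  cfg <- sim_config(n_proteins = 600, shift_fraction = 1, delta_tm_mean = 3,
                    delta_tm_sd = 0.5, seed = 33L)
  sim <- simulate_tpp(cfg)
  d <- sim$truth$delta_tm_true[sim$truth$condition == "vehicle"]
  se <- cfg$delta_tm_sd / sqrt(length(d))
  expect_lt(abs(mean(d) - cfg$delta_tm_mean), 3 * se)
})

test_that("melt tables round-trip through write/read and count correctly", {
  sim <- simulate_tpp(sim_config(n_proteins = 1, seed = 6L))
  expect_equal(nrow(sim$profiles), 1 * 2 * 2 * 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_melt_table(sim$profiles, path)
  back <- read_melt_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$profiles))
  expect_error(write_melt_table(sim$profiles[0, ], path),
               class = "tppshift_input_error")
})
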