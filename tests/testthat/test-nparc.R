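test_that("F-statistic and p-value match hand arithmetic", {
  res <- nparc_f_test(rss0 = 2, rss1 = 1, n_obs = 40)
  expect_equal(res$f_stat, (1 / 3) / (1 / 34))
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 34)
  expect_equal(res$p_value, pf((1 / 3) / (1 / 34), 3, 34, lower.tail = FALSE))
  ## equal fits carry no evidence
  eq <- nparc_f_test(rss0 = 1, rss1 = 1, n_obs = 40)
  expect_equal(eq$f_stat, 0)
  expect_equal(eq$p_value, 1)
  ## nesting violations within tolerance clamp to zero
  expect_equal(nparc_f_test(0.99, 1, 40)$f_stat, 0)
})

test_that("degenerate F-test inputs are handled explicitly", {
  expect_error(nparc_f_test(2, 1, n_obs = 6), class = "tppshift_input_error")
  expect_warning(res <- nparc_f_test(2, 0, n_obs = 40), "floored")
  expect_equal(res$p_value, 1e-300)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "tppshift_input_error")
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p))
  }
})

test_that("hit tiers follow the nominal and adjusted thresholds", {
  res <- tibble::tibble(p_value = c(0.2, 0.04, 0.005),
                        p_adjusted = c(0.3, 0.12, 0.04))
  out <- classify_hits(res)
  expect_equal(as.character(out$tier), c("none", "significant", "prime"))
  hs <- hit_summary(out)
  expect_equal(hs$n_significant, 2)
  expect_equal(hs$n_marked, 1)
  expect_equal(hs$n_prime, 1)
  empty <- hit_summary(classify_hits(res[0, ]))
  expect_equal(unlist(empty[, -1]), c(n_tested = 0, n_significant = 0,
                                      n_marked = 0, n_prime = 0))
})

test_that("null and alternative fits nest and agree on identical data", {
  sim <- simulate_tpp(sim_config(n_proteins = 2, noise_sd = 0,
                                 shift_fraction = 0, seed = 3L))
  prof <- sim$profiles[sim$profiles$protein_id == "P0001", ]
  null <- nparc_fit_null(prof)
  alt <- nparc_fit_alternative(prof)
  expect_lt(null$rss0, 1e-8)
  expect_lt(alt$rss1, 1e-8)
  expect_error(nparc_fit_null(prof[prof$condition == "vehicle", ]),
               class = "tppshift_input_error")
})

test_that("a noiseless shifted pair is explained by the alternative only", {
  temps <- seq(37, 67, length.out = 10)
  prof <- dplyr::bind_rows(
    data.frame(protein_id = "S", condition = "vehicle", replicate = 1L,
               temperature_c = temps,
               rel_abundance = melt_sigmoid(temps, 550, 10, 0.05)),
    data.frame(protein_id = "S", condition = "treatment", replicate = 1L,
               temperature_c = temps,
               rel_abundance = melt_sigmoid(temps, 590, 10, 0.05)))
  null <- nparc_fit_null(prof)
  alt <- nparc_fit_alternative(prof)
  expect_lt(alt$rss1, 1e-8)
  expect_gt(null$rss0, 100 * max(alt$rss1, 1e-12))
})

test_that("rss1 <= rss0 within tolerance across noisy simulated proteins", {
  sim <- simulate_tpp(sim_config(n_proteins = 60, shift_fraction = 0.2,
                                 seed = 17L))
  res <- nparc_test(sim$profiles, df_mode = "theoretical")
  tested <- res[res$testable, ]
  expect_gt(nrow(tested), 50)
  expect_true(all(tested$rss1 <= tested$rss0 + 1e-8))
  ## BH over tested hypotheses only, order-preserving
  expect_equal(tested$p_adjusted, bh_brute_force(tested$p_value))
  expect_true(all(tested$p_adjusted >= tested$p_value - 1e-12))
})

test_that("realized false-discovery proportion stays controlled in mixtures", {
  ## 10% shifters, dTm = 4 C, noise 0.04; FDP among adjusted-p hits pooled
  ## over 20 independent simulations
  false_hits <- 0L
  total_hits <- 0L
  for (s in 1:20) {
    sim <- simulate_tpp(sim_config(n_proteins = 100, shift_fraction = 0.1,
                                   delta_tm_mean = 4, delta_tm_sd = 0.5,
                                   noise_sd = 0.04, seed = 4000L + s))
    res <- nparc_test(sim$profiles)
    hits <- res$protein_id[!is.na(res$p_adjusted) & res$p_adjusted < 0.1]
    truth <- sim$truth[sim$truth$condition == "vehicle", ]
    shifters <- truth$protein_id[truth$shifter]
    false_hits <- false_hits + sum(!hits %in% shifters)
    total_hits <- total_hits + length(hits)
  }
  expect_gt(total_hits, 50)
  expect_lte(false_hits / total_hits, 0.2)
})

test_that("untestable proteins are excluded from the adjustment", {
  sim <- simulate_tpp(sim_config(n_proteins = 30, seed = 23L))
  prof <- sim$profiles
  ## cripple one protein: drop its treatment condition entirely
  prof <- prof[!(prof$protein_id == "P0001" &
                   prof$condition == "treatment"), ]
  res <- suppressWarnings(nparc_test(prof, df_mode = "theoretical"))
  expect_false(res$testable[res$protein_id == "P0001"])
  expect_true(is.na(res$p_value[res$protein_id == "P0001"]))
  tested <- res[res$testable, ]
  expect_equal(tested$p_adjusted, bh_brute_force(tested$p_value))
})
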