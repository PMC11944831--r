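test_that("formulas parse into element counts", {
  expect_equal(parse_formula("C27H32O14"), c(C = 27, H = 32, O = 14))
  expect_equal(parse_formula("C19H15NO4"), c(C = 19, H = 15, N = 1, O = 4))
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_error(parse_formula("C27H32O14x"), class = "tppshift_parse_error")
  expect_error(parse_formula("Xy3"), class = "tppshift_parse_error")
  expect_error(parse_formula(""), class = "tppshift_parse_error")
})

test_that("monoisotopic masses sum the standard atomic masses", {
  expect_equal(monoisotopic_mass(numeric(0)), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  ## independent subtotals: 27 C = 324 exactly, 14 O = 223.92880468
  expect_equal(monoisotopic_mass("C27H32O14"),
               27 * 12 + 32 * 1.00782503 + 14 * 15.99491462)
  expect_equal(monoisotopic_mass("C27H32O14"), 580.179206, tolerance = 1e-6)
  expect_error(monoisotopic_mass(c(Zz = 3)), class = "tppshift_parse_error")
})

test_that("adduct m/z reproduces the published measured values", {
  mass <- monoisotopic_mass("C27H32O14")
  neg <- adduct_mz(mass, "[M-H]-")
  pos <- adduct_mz(mass, "[M+H]+")
  expect_equal(neg, 579.171930, tolerance = 1e-6)
  expect_equal(pos, 581.186482, tolerance = 1e-6)
  ## agreement with the measured narirutin ions in both modes
  expect_lt(ppm_error(579.17223, neg), 5)
  expect_lt(ppm_error(581.18599, pos), 5)
  expect_error(adduct_mz(0, "[M-H]-"), class = "tppshift_input_error")
  expect_error(adduct_mz(100, "[M+Na]+"), class = "tppshift_input_error")
})

test_that("ppm error is the relative deviation in parts per million", {
  expect_equal(ppm_error(579.17223, 579.171930), 0.52, tolerance = 0.02)
  expect_equal(ppm_error(100, 100), 0)
  ## berberrubine: measured vs theoretical protonated ion
  th <- adduct_mz(monoisotopic_mass("C19H15NO4"), "[M+H]+")
  expect_lt(ppm_error(322.10752, th), 1)
  expect_error(ppm_error(-1, 100), class = "tppshift_input_error")
})

test_that("every packaged compound row matches theory within 5 ppm", {
  for (file in c("table1_negative.tsv", "table2_positive.tsv",
                 "table3_binding.tsv")) {
    tab <- annotate_theoretical_mz(read_fixture(file), ppm_tol = 5)
    expect_true(all(tab$mz_ok), label = file)
  }
})

test_that("main-component filter applies strict score and ratio cuts", {
  t1 <- read_fixture("table1_negative.tsv")
  kept <- filter_main_components(t1)
  expect_equal(nrow(kept), 32)
  expect_true(setequal(kept$name, t1$name))
  ## idempotent and a subset of its input
  expect_equal(filter_main_components(kept), kept)
  boundary <- tibble::tibble(
    name = c("at-score-threshold", "at-ratio-threshold", "clearly-in"),
    formula = "H2O", mz = 1,
    mzvault_score = c(80, 85, 88),
    sample_control_ratio = c(25, 20, 30))
  expect_equal(filter_main_components(boundary)$name, "clearly-in")
  expect_error(filter_main_components(dplyr::select(boundary,
                                                    -sample_control_ratio)),
               class = "tppshift_validation_error")
})

test_that("binding-component filter drops low scores and blank hits", {
  records <- tibble::tibble(
    name = c("compA", "compB", "compC", "compD"),
    mzvault_score = c(75, 95, 70, 90))
  blank <- tibble::tibble(name = c("COMPB ", "other"))
  kept <- filter_binding_components(records, blank)
  ## compB present in blank (case/whitespace-insensitively); compC at the
  ## exact threshold
  expect_equal(kept$name, c("compA", "compD"))
})

test_that("cross-mode deduplication counts unique names with provenance", {
  neg <- filter_main_components(read_fixture("table1_negative.tsv"))
  pos <- filter_main_components(read_fixture("table2_positive.tsv"))
  uniq <- deduplicate_across_modes(neg, pos)
  expect_equal(nrow(uniq), 54)
  expect_equal(sum(uniq$n_modes == 2), nrow(neg) + nrow(pos) - 54)
  narirutin <- uniq[uniq$name == "Narirutin", ]
  expect_equal(narirutin$modes, "negative+positive")
  expect_false(is.na(narirutin$mz_negative))
  expect_false(is.na(narirutin$mz_positive))
  ## commutative (as a name set) and idempotent in each argument
  swapped <- deduplicate_across_modes(pos, neg)
  expect_setequal(uniq$name, swapped$name)
  expect_equal(nrow(deduplicate_across_modes(neg, neg)), nrow(neg))
  ## small synthetic cases
  a <- tibble::tibble(name = c("x", "y", "z"))
  b <- tibble::tibble(name = c("p", "q", "r", "s"))
  expect_equal(nrow(deduplicate_across_modes(a, b)), 7)
  one <- deduplicate_across_modes(tibble::tibble(name = "x", mz = 1),
                                  tibble::tibble(name = "X", mz = 2))
  expect_equal(nrow(one), 1)
  expect_equal(one$mz_negative, 1)
  expect_equal(one$mz_positive, 2)
})
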