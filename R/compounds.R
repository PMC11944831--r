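## Monoisotopic atomic masses (Da) for the elements occurring in the
## supported small-molecule formulas.
MONOISOTOPIC_MASSES <- c(C = 12, H = 1.00782503, N = 14.00307401,
                         O = 15.99491462, S = 31.97207117, P = 30.97376200)

PROTON_MASS <- 1.007276

## formate anion HCOO- : HCOOH minus a proton
FORMATE_DELTA <- 2 * 1.00782503 + 12 + 2 * 15.99491462 - PROTON_MASS

ADDUCT_DELTAS <- c("[M+H]+" = +PROTON_MASS,
                   "[M-H]-" = -PROTON_MASS,
                   "[M+HCOO]-" = +FORMATE_DELTA)

#' Parse an elemental formula
#'
#' Parses formulas of the `C27H32O14` kind (elements C, H, N, O, S, P;
#' implicit count 1) into a named count vector.
#'
#' @param formula A single formula string.
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C19H15NO4")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || !is.character(formula) || is.na(formula) ||
      !nzchar(formula)) {
    abort("`formula` must be a single non-empty string",
          class = "tppshift_parse_error")
  }
  tokens <- regmatches(formula,
                       gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    bad <- substr(gsub(paste0("^", paste(tokens, collapse = "")), "",
                       formula), 1, 8)
    abort(sprintf("malformed formula '%s' (cannot parse at '%s')",
                  formula, bad),
          class = "tppshift_parse_error")
  }
  counts <- numeric(0)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    if (!el %in% names(MONOISOTOPIC_MASSES)) {
      abort(sprintf("unknown element '%s' in formula '%s'", el, formula),
            class = "tppshift_parse_error")
    }
    prev <- if (el %in% names(counts)) counts[[el]] else 0
    counts[el] <- prev + if (nzchar(n)) as.numeric(n) else 1
  }
  counts
}

#' Monoisotopic mass of a formula or element-count vector
#'
#' Sum of element counts times monoisotopic atomic masses (C = 12 exactly,
#' H = 1.00782503, N = 14.00307401, O = 15.99491462, S = 31.97207117,
#' P = 30.97376200 Da).
#'
#' @param x Formula string(s), or a named numeric vector of element counts
#'   as produced by [parse_formula()].
#' @return Monoisotopic mass(es) in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C27H32O14")  # 580.179206
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(f) monoisotopic_mass(parse_formula(f)),
                  numeric(1), USE.NAMES = FALSE))
  }
  if (length(x) == 0) return(0)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("element counts must be a named vector", class = "tppshift_parse_error")
  }
  if (any(x < 0)) {
    abort("element counts must be nonnegative", class = "tppshift_parse_error")
  }
  unknown <- setdiff(names(x), names(MONOISOTOPIC_MASSES))
  if (length(unknown) > 0) {
    abort(paste0("no monoisotopic mass for element(s): ",
                 paste(unknown, collapse = ", ")),
          class = "tppshift_parse_error")
  }
  sum(x * MONOISOTOPIC_MASSES[names(x)])
}

#' Theoretical m/z of a singly charged adduct
#'
#' Supported adducts: `[M+H]+` (mass + 1.007276), `[M-H]-`
#' (mass - 1.007276) and `[M+HCOO]-` (mass + 44.998203, the formate adduct
#' commonly formed by neutral glycosides in negative mode with formic-acid
#' mobile phases).
#'
#' @param mass Neutral monoisotopic mass(es) in Da, > 0.
#' @param adduct Adduct label(s), recycled against `mass`.
#' @return m/z value(s).
#' @examples
#' adduct_mz(580.179206, "[M-H]-")  # 579.17193
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+") {
  if (any(!is.finite(mass) | mass <= 0)) {
    abort("`mass` must be positive", class = "tppshift_input_error")
  }
  bad <- setdiff(unique(adduct), names(ADDUCT_DELTAS))
  if (length(bad) > 0) {
    abort(paste0("unsupported adduct label(s): ", paste(bad, collapse = ", "),
                 " (supported: ", paste(names(ADDUCT_DELTAS), collapse = ", "),
                 ")"),
          class = "tppshift_input_error")
  }
  mass + unname(ADDUCT_DELTAS[adduct])
}

#' Relative mass error in parts per million
#'
#' `|mz_a - mz_b| / mz_b * 1e6`, with `mz_b` the reference (theoretical)
#' value.
#'
#' @param mz_a,mz_b Positive m/z values (vectorised).
#' @return ppm error(s).
#' @export
ppm_error <- function(mz_a, mz_b) {
  if (any(!is.finite(mz_a) | mz_a <= 0) || any(!is.finite(mz_b) | mz_b <= 0)) {
    abort("m/z values must be positive", class = "tppshift_input_error")
  }
  abs(mz_a - mz_b) / mz_b * 1e6
}

#' Read a compound identification table
#'
#' Reads a CSV or TSV with at least `name`, `formula`, `mz` columns and
#' optionally `rt_min`, `mzvault_score`, `sample_control_ratio`,
#' `ion_mode`, `adduct`. The packaged fixtures (see [tppshift_example()])
#' use this layout.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A tibble of compound records.
#' @export
read_compound_table <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  missing <- setdiff(c("name", "formula", "mz"), names(out))
  if (length(missing) > 0) {
    abort(paste0("compound table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tppshift_input_error")
  }
  out
}

#' Path to a packaged example data file
#'
#' The package ships the published compound tables as plain-text fixtures:
#' `table1_negative.tsv` and `table2_positive.tsv` (main-component tables
#' in the two ion modes), `table3_binding.tsv` (ADAM17-binding components;
#' per-row ion mode and adduct inferred from the printed m/z) and
#' `table4_docking.tsv` (docking scores).
#'
#' @param file File name; if missing, lists available files.
#' @return Full path to the file.
#' @export
tppshift_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tppshift")))
  }
  path <- system.file("extdata", file, package = "tppshift")
  if (!nzchar(path)) {
    abort(sprintf("no packaged file '%s'", file), class = "tppshift_input_error")
  }
  path
}

#' Annotate compound records with theoretical m/z and ppm error
#'
#' Computes the monoisotopic mass from each record's formula, derives the
#' theoretical m/z for its adduct (taken from an `adduct` column when
#' present, otherwise the mode default: `[M+H]+` for positive,
#' `[M-H]-` for negative) and flags records whose measured m/z agrees
#' within `ppm_tol`.
#'
#' @param records Compound tibble with `name`, `formula`, `mz` and
#'   `ion_mode` (and optionally `adduct`) columns.
#' @param ppm_tol Agreement tolerance in ppm (default 5, Orbitrap-typical).
#' @return `records` with `mz_theoretical`, `ppm` and `mz_ok` columns.
#' @export
annotate_theoretical_mz <- function(records, ppm_tol = 5) {
  adduct <- if ("adduct" %in% names(records)) records$adduct
            else ifelse(records$ion_mode == "positive", "[M+H]+", "[M-H]-")
  mass <- monoisotopic_mass(records$formula)
  records |>
    dplyr::mutate(mz_theoretical = adduct_mz(mass, adduct),
                  ppm = ppm_error(.data$mz, .data$mz_theoretical),
                  mz_ok = .data$ppm <= ppm_tol)
}

#' Filter main components by identification score and enrichment ratio
#'
#' Keeps records whose spectral-library score strictly exceeds
#' `score_min` and whose sample/control abundance ratio strictly exceeds
#' `ratio_min` ("over 80" / "exceeding 20" are strict inequalities:
#' records at exactly the threshold are dropped). Idempotent.
#'
#' @param records Compound tibble with `mzvault_score` and
#'   `sample_control_ratio` columns.
#' @param score_min Minimum mzVault best-match score (default 80).
#' @param ratio_min Minimum sample/control ratio (default 20); set to
#'   `NULL` to disable the ratio filter.
#' @return The kept records.
#' @export
filter_main_components <- function(records, score_min = 80, ratio_min = 20) {
  if (!"mzvault_score" %in% names(records)) {
    abort("records need an `mzvault_score` column",
          class = "tppshift_validation_error")
  }
  out <- dplyr::filter(records, .data$mzvault_score > score_min)
  if (!is.null(ratio_min)) {
    if (!"sample_control_ratio" %in% names(records) ||
        anyNA(records$sample_control_ratio)) {
      abort("ratio filter enabled but `sample_control_ratio` is missing",
            class = "tppshift_validation_error")
    }
    out <- dplyr::filter(out, .data$sample_control_ratio > ratio_min)
  }
  out
}

#' Filter binding components against a blank control
#'
#' Keeps records whose score strictly exceeds `score_min` and whose name
#' is absent (case-insensitively, after whitespace normalization) from the
#' blank-control record set — the criteria used to call components that
#' bind the immobilised target rather than the sensor.
#'
#' @param records Candidate compound tibble with `name` and
#'   `mzvault_score`.
#' @param blank Blank-control compound tibble with a `name` column.
#' @param score_min Minimum score, strict (default 70).
#' @return The kept records.
#' @export
filter_binding_components <- function(records, blank, score_min = 70) {
  if (!"mzvault_score" %in% names(records)) {
    abort("records need an `mzvault_score` column",
          class = "tppshift_validation_error")
  }
  blank_names <- normalize_compound_name(blank$name)
  dplyr::filter(records,
                .data$mzvault_score > score_min,
                !normalize_compound_name(.data$name) %in% blank_names)
}

normalize_compound_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Deduplicate compounds across ionisation modes
#'
#' Unions two mode-specific compound tables keyed by case-insensitive,
#' whitespace-normalized name. Each unique compound keeps per-mode
#' provenance: the modes it was observed in and the measured m/z in each.
#' Commutative and idempotent.
#'
#' @param neg_records,pos_records Compound tibbles with `name` columns and
#'   optionally `mz` and `ion_mode`.
#' @return Tibble with one row per unique compound: `name` (first-seen
#'   spelling), `modes`, `n_modes`, `mz_negative`, `mz_positive`.
#' @export
deduplicate_across_modes <- function(neg_records, pos_records) {
  tag <- function(d, default_mode) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    d <- tibble::as_tibble(d)
    if (!"ion_mode" %in% names(d)) d$ion_mode <- default_mode
    if (!"mz" %in% names(d)) d$mz <- NA_real_
    d[, c("name", "ion_mode", "mz")]
  }
  all <- dplyr::bind_rows(tag(neg_records, "negative"),
                          tag(pos_records, "positive"))
  if (is.null(all) || nrow(all) == 0) {
    return(tibble::tibble(name = character(), modes = character(),
                          n_modes = integer(), mz_negative = numeric(),
                          mz_positive = numeric()))
  }
  all |>
    dplyr::mutate(key = normalize_compound_name(.data$name)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      name = dplyr::first(.data$name),
      modes = paste(sort(unique(.data$ion_mode)), collapse = "+"),
      n_modes = length(unique(.data$ion_mode)),
      mz_negative = dplyr::first(.data$mz[.data$ion_mode == "negative"]) %||% NA_real_,
      mz_positive = dplyr::first(.data$mz[.data$ion_mode == "positive"]) %||% NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$key) |>
    dplyr::select(-"key")
}
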