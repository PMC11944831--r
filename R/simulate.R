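#' Simulate a TPP dataset with known ground truth
#'
#' Generates TMT-style relative-abundance melting profiles for
#' `n_proteins` proteins under two conditions. Baseline sigmoid parameters
#' `(a, b, plateau)` are drawn from the configured ranges, rejecting draws
#' whose melting temperature falls outside `tm_range`. A configured
#' fraction of proteins are true "shifters": their treatment-condition
#' slope parameter is re-derived so the closed-form Tm moves by exactly the
#' injected delta Tm while `b` and `plateau` are held fixed, keeping the
#' ground truth exact. Observed abundances are the true curve times
#' `(1 + e)`, `e ~ N(0, noise_sd)`, truncated at 0; replicates are
#' independent noise redraws around the same true curve. With
#' `noise_sd = 0` the output equals the model curve exactly.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `tpp_simulation`: a list with
#'   \describe{
#'     \item{profiles}{tibble of `protein_id`, `condition`, `replicate`,
#'       `temperature_c`, `rel_abundance` (one row per measured point).}
#'     \item{truth}{tibble of per-protein, per-condition true parameters
#'       `a`, `b`, `plateau`, `tm_c`, plus `shifter` flag and
#'       `delta_tm_true` (0 for non-shifters).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_tpp(sim_config(n_proteins = 5, seed = 7))
#' head(sim$profiles)
#' @export
simulate_tpp <- function(config) {
  if (!inherits(config, "tpp_sim_config")) {
    violations <- validate_sim_config(config)
    if (length(violations) > 0) {
      abort(paste0("invalid simulation configuration:\n",
                   paste0("- ", violations, collapse = "\n")),
            class = "tppshift_config_error")
    }
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  pars <- draw_baseline_params(n, config)
  shifter <- runif(n) < config$shift_fraction
  dtm <- ifelse(shifter,
                rnorm(n, config$delta_tm_mean, config$delta_tm_sd), 0)

  tm_v <- compute_tm(pars$a, pars$b, pars$plateau)
  a_trt <- ifelse(shifter, tm_to_a(tm_v + dtm, pars$b, pars$plateau), pars$a)

  truth <- dplyr::bind_rows(
    tibble::tibble(protein_id = ids, condition = config$conditions[1],
                   a = pars$a, b = pars$b, plateau = pars$plateau,
                   tm_c = tm_v, shifter = shifter, delta_tm_true = dtm),
    tibble::tibble(protein_id = ids, condition = config$conditions[2],
                   a = a_trt, b = pars$b, plateau = pars$plateau,
                   tm_c = compute_tm(a_trt, pars$b, pars$plateau),
                   shifter = shifter, delta_tm_true = dtm)
  ) |>
    dplyr::arrange(.data$protein_id, match(.data$condition, config$conditions))

  temps <- config$temperatures
  nt <- length(temps)
  grid <- tidyr::expand_grid(
    protein_id = ids,
    condition = config$conditions,
    replicate = seq_len(config$n_replicates)
  )
  profiles <- grid |>
    dplyr::left_join(truth[, c("protein_id", "condition", "a", "b", "plateau")],
                     by = c("protein_id", "condition")) |>
    tidyr::expand_grid(temperature_c = temps) |>
    dplyr::mutate(true_abundance =
                    melt_sigmoid(.data$temperature_c, .data$a, .data$b,
                                 .data$plateau))
  eps <- rnorm(nrow(profiles), 0, config$noise_sd)
  profiles <- profiles |>
    dplyr::mutate(rel_abundance = pmax(.data$true_abundance * (1 + eps), 0)) |>
    dplyr::select("protein_id", "condition", "replicate", "temperature_c",
                  "rel_abundance")

  structure(list(profiles = profiles, truth = truth, config = config),
            class = "tpp_simulation")
}

## rejection sampling of (a, b, plateau) until Tm lies in tm_range
draw_baseline_params <- function(n, config) {
  a <- b <- plateau <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    ca <- runif(m, config$a_range[1], config$a_range[2])
    cb <- runif(m, config$b_range[1], config$b_range[2])
    cp <- runif(m, config$plateau_range[1], config$plateau_range[2])
    tm <- compute_tm(ca, cb, cp)
    ok <- !is.na(tm) & tm >= config$tm_range[1] & tm <= config$tm_range[2]
    k <- sum(ok)
    if (k > 0) {
      idx <- filled + seq_len(k)
      a[idx] <- ca[ok]; b[idx] <- cb[ok]; plateau[idx] <- cp[ok]
      filled <- filled + k
    }
  }
  list(a = a, b = b, plateau = plateau)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.tpp_simulation <- function(x, ...) {
  cat("<tpp_simulation>\n")
  print(x$config)
  cat(sprintf("  %d profile rows, %d true shifters\n",
              nrow(x$profiles), sum(x$truth$shifter) / 2L))
  invisible(x)
}

#' Write a long-format melt table
#'
#' Writes profiles as a tab-separated table with columns exactly
#' `protein_id`, `condition`, `replicate`, `temperature_c`,
#' `rel_abundance`, round-tripping losslessly through
#' [read_melt_table()].
#'
#' @param profiles Data frame of melt profiles (the `profiles` element of a
#'   [simulate_tpp()] result, or any table with the same columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melt_table <- function(profiles, path) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    abort("cannot write an empty melt table", class = "tppshift_input_error")
  }
  check_profile_columns(profiles)
  readr::write_tsv(profiles[, c("protein_id", "condition", "replicate",
                                "temperature_c", "rel_abundance")], path)
  invisible(path)
}

#' Read a long-format melt table
#'
#' @param path Path to a TSV written by [write_melt_table()] (or any file
#'   with the same five columns).
#' @return A tibble of melt profiles.
#' @export
read_melt_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           condition = readr::col_character(),
                           replicate = readr::col_integer(),
                           temperature_c = readr::col_double(),
                           rel_abundance = readr::col_double()))
  check_profile_columns(out)
  out
}
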