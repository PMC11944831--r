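#' Configuration for the synthetic TPP data generator
#'
#' Bundles and validates all parameters of [simulate_tpp()]. Defaults
#' describe a standard TMT-style TPP design: ten temperatures from 37 to
#' 67 degrees C, vehicle vs treatment, two biological replicates, baseline
#' parameters drawn so that true melting temperatures fall in 45-70 degrees
#' C (the range observed for the human proteome), a 10% fraction of true
#' shifters with Tm shifts around +3 degrees C, and 5% multiplicative noise.
#'
#' @param n_proteins Number of simulated proteins.
#' @param temperatures Strictly increasing temperature grid in degrees C;
#'   the first value is the reference channel.
#' @param conditions Pair of condition labels, vehicle first.
#' @param n_replicates Biological replicates per condition.
#' @param shift_fraction Proportion of proteins carrying a true Tm shift,
#'   in `[0, 1]`.
#' @param delta_tm_mean,delta_tm_sd Mean and standard deviation (degrees C)
#'   of the normal distribution the injected Tm shifts are drawn from.
#' @param noise_sd Standard deviation of the multiplicative Gaussian noise
#'   on relative abundance (observed = true x (1 + e), truncated at 0).
#' @param a_range,b_range,plateau_range Sampling ranges for the baseline
#'   sigmoid parameters; draws are rejected until the implied Tm falls in
#'   `tm_range`.
#' @param tm_range Admissible range for baseline melting temperatures.
#' @param seed Integer seed; identical configurations give identical data.
#' @return A `tpp_sim_config` list.
#' @seealso [simulate_tpp()]
#' @export
sim_config <- function(n_proteins = 100,
                       temperatures = seq(37, 67, length.out = 10),
                       conditions = c("vehicle", "treatment"),
                       n_replicates = 2,
                       shift_fraction = 0.1,
                       delta_tm_mean = 3,
                       delta_tm_sd = 0.5,
                       noise_sd = 0.05,
                       a_range = c(430, 680),
                       b_range = c(9, 11),
                       plateau_range = c(0, 0.15),
                       tm_range = c(45, 70),
                       seed = 1L) {
  cfg <- structure(
    list(n_proteins = n_proteins, temperatures = temperatures,
         conditions = conditions, n_replicates = n_replicates,
         shift_fraction = shift_fraction, delta_tm_mean = delta_tm_mean,
         delta_tm_sd = delta_tm_sd, noise_sd = noise_sd,
         a_range = a_range, b_range = b_range,
         plateau_range = plateau_range, tm_range = tm_range,
         seed = as.integer(seed)),
    class = "tpp_sim_config")
  violations <- validate_sim_config(cfg)
  if (length(violations) > 0) {
    abort(paste0("invalid simulation configuration:\n",
                 paste0("- ", violations, collapse = "\n")),
          class = "tppshift_config_error")
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `tpp_sim_config` (or plain list with the same fields).
#' @return Character vector of violations; empty when valid. Each message
#'   names the offending field.
#' @export
validate_sim_config <- function(cfg) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(cfg$n_proteins) && length(cfg$n_proteins) == 1 &&
        cfg$n_proteins >= 1 && cfg$n_proteins == floor(cfg$n_proteins),
      "n_proteins: must be a positive integer")
  chk(is.numeric(cfg$temperatures) && length(cfg$temperatures) >= 5 &&
        all(diff(cfg$temperatures) > 0) && all(cfg$temperatures > 0),
      "temperatures: need >= 5 strictly increasing positive values")
  chk(is.character(cfg$conditions) && length(cfg$conditions) == 2 &&
        !anyDuplicated(cfg$conditions),
      "conditions: need exactly two distinct labels")
  chk(is.numeric(cfg$n_replicates) && cfg$n_replicates >= 1 &&
        cfg$n_replicates == floor(cfg$n_replicates),
      "n_replicates: must be a positive integer")
  chk(is.numeric(cfg$shift_fraction) && cfg$shift_fraction >= 0 &&
        cfg$shift_fraction <= 1,
      "shift_fraction: must lie in [0, 1]")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0,
      "noise_sd: must be >= 0")
  chk(is.numeric(cfg$delta_tm_sd) && cfg$delta_tm_sd >= 0,
      "delta_tm_sd: must be >= 0")
  for (f in c("a_range", "b_range", "plateau_range", "tm_range")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 2 &&
          cfg[[f]][1] <= cfg[[f]][2],
        paste0(f, ": must be a non-decreasing length-2 range"))
  }
  if (is.numeric(cfg$plateau_range) && length(cfg$plateau_range) == 2) {
    chk(cfg$plateau_range[1] >= 0 && cfg$plateau_range[2] < 0.5,
        "plateau_range: must lie in [0, 0.5) so Tm is defined")
  }
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed: must be a single integer")
  v
}

#' @export
print.tpp_sim_config <- function(x, ...) {
  cat("<tpp_sim_config>\n")
  cat(sprintf("  %d proteins, %d temperatures (%.4g-%.4g C), %s vs %s, %d replicate(s)\n",
              x$n_proteins, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$conditions[1], x$conditions[2],
              x$n_replicates))
  cat(sprintf("  shifters: %.0f%% with dTm ~ N(%.3g, %.3g) C; noise_sd = %.3g; seed = %d\n",
              100 * x$shift_fraction, x$delta_tm_mean, x$delta_tm_sd,
              x$noise_sd, x$seed))
  invisible(x)
}
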