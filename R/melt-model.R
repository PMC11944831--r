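#' Three-parameter sigmoid melting model
#'
#' Predicted non-denatured fraction at temperature `temperature_c` (degrees
#' Celsius) for the standard TPP melting model
#' \deqn{f(T) = \frac{1 - plateau}{1 + e^{b - a/T}} + plateau.}
#' For `a, b > 0` the curve decreases strictly from values near 1 at low
#' temperature towards `plateau` at high temperature. Temperatures are in
#' degrees Celsius, not Kelvin: `a` scales with the temperature unit, so
#' parameters are not transferable between unit conventions.
#'
#' @param temperature_c Temperature in degrees Celsius; must be positive.
#' @param a Slope numerator (Celsius-scaled), > 0.
#' @param b Dimensionless offset, > 0.
#' @param plateau Lower asymptote, in `[0, 1)`.
#' @return Numeric vector of predicted relative abundances.
#' @examples
#' melt_sigmoid(55, a = 550, b = 10, plateau = 0.2)  # exactly 0.6
#' @export
melt_sigmoid <- function(temperature_c, a, b, plateau) {
  if (any(temperature_c <= 0)) {
    abort("`temperature_c` must be positive (degrees Celsius).",
          class = "tppshift_domain_error")
  }
  (1 - plateau) / (1 + exp(b - a / temperature_c)) + plateau
}

#' Melting temperature from fitted sigmoid parameters
#'
#' Closed-form half-denaturation point of [melt_sigmoid()]: the temperature
#' at which the curve crosses 0.5,
#' \deqn{T_m = a / (b - \log(0.5 / (0.5 - plateau))).}
#' Undefined (`NA`) when `plateau >= 0.5` (the curve never reaches 0.5) or
#' when the crossing falls outside the extrapolation `window`, in which case
#' the nominal crossing would be an unreliable extrapolation.
#'
#' @param a,b,plateau Sigmoid parameters (vectorised).
#' @param window Optional length-2 numeric: Tm values outside it become `NA`.
#' @return Tm in degrees Celsius, or `NA` where undefined.
#' @examples
#' compute_tm(550, 10, 0)    # 55
#' compute_tm(550, 10, 0.2)  # ~57.96
#' compute_tm(550, 10, 0.6)  # NA: curve never reaches 0.5
#' @export
compute_tm <- function(a, b, plateau, window = NULL) {
  reach <- !is.na(plateau) & plateau < 0.5
  denom <- ifelse(reach, b - log(0.5 / (0.5 - ifelse(reach, plateau, 0))),
                  NA_real_)
  tm <- ifelse(reach & denom > 0, a / denom, NA_real_)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    tm[!is.na(tm) & (tm < window[1] | tm > window[2])] <- NA_real_
  }
  tm
}

## inverse of compute_tm in `a`: slope numerator that places Tm at `tm`
## given b and plateau; used by the generator to inject exact Tm shifts
tm_to_a <- function(tm, b, plateau) {
  tm * (b - log(0.5 / (0.5 - plateau)))
}

#' Normalize melt profiles to the reference temperature
#'
#' Divides every abundance within a protein x condition x replicate profile
#' by its abundance at the reference temperature (the lowest temperature by
#' default, 37 degrees C in the standard design), so the reference point
#' equals exactly 1. Idempotent.
#'
#' @param profiles Data frame with columns `protein_id`, `condition`,
#'   `replicate`, `temperature_c`, `rel_abundance`.
#' @param reference_temp Reference temperature; defaults to the minimum
#'   temperature present in each profile.
#' @return A tibble with the same columns, abundances rescaled.
#' @export
normalize_to_reference <- function(profiles, reference_temp = NULL) {
  check_profile_columns(profiles)
  profiles |>
    dplyr::group_by(.data$protein_id, .data$condition, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      ref_t <- reference_temp %||% min(d$temperature_c)
      i <- which(abs(d$temperature_c - ref_t) < 1e-9)
      if (length(i) != 1L) {
        abort(sprintf("profile %s/%s: reference temperature %.6g missing",
                      key$protein_id, key$condition, ref_t),
              class = "tppshift_normalization_error")
      }
      ref <- d$rel_abundance[i]
      if (!is.finite(ref) || ref <= 0) {
        abort(sprintf("profile %s/%s: reference abundance must be > 0",
                      key$protein_id, key$condition),
              class = "tppshift_normalization_error")
      }
      d$rel_abundance <- d$rel_abundance / ref
      d
    }) |>
    dplyr::ungroup()
}

check_profile_columns <- function(profiles,
                                  cols = c("protein_id", "condition", "replicate",
                                           "temperature_c", "rel_abundance")) {
  missing <- setdiff(cols, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("melt table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tppshift_input_error")
  }
  invisible(profiles)
}
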