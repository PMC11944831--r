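## Bounded Levenberg-Marquardt fit of the three-parameter melting sigmoid.
## Multistart: a data-driven start (midpoint crossing + minimum abundance)
## plus deterministic perturbations; the best-RSS solution is kept. Local
## optima in per-condition fits would otherwise inflate RSS1 and distort
## the downstream F-test.
fit_sigmoid_ls <- function(temperature, abundance, extra_starts = NULL) {
  ok <- is.finite(temperature) & is.finite(abundance)
  temperature <- temperature[ok]; abundance <- abundance[ok]
  p0 <- min(max(min(abundance), 0), 0.4)
  ymid <- (max(abundance) + p0) / 2
  idx <- which(abundance <= ymid)[1]
  tm0 <- if (is.na(idx)) max(temperature) else temperature[idx]
  starts <- c(list(
    list(a = tm0 * 10, b = 10, plateau = p0),
    list(a = tm0 * 8,  b = 8,  plateau = p0 / 2),
    list(a = tm0 * 12, b = 12, plateau = min(p0 + 0.05, 0.4)),
    list(a = 550,      b = 10, plateau = 0.05)
  ), extra_starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        abundance ~ (1 - plateau) / (1 + exp(b - a / temperature)) + plateau,
        data = data.frame(temperature = temperature, abundance = abundance),
        start = st,
        lower = c(a = 1e-6, b = 1e-6, plateau = 0),
        upper = c(a = 5000, b = 100, plateau = 0.999),
        control = minpack.lm::nls.lm.control(maxiter = 150))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        cf <- coef(fit)
        best <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                     plateau = unname(cf["plateau"]), rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(list(a = NA_real_, b = NA_real_, plateau = NA_real_,
                rss = NA_real_, converged = FALSE))
  }
  c(best, converged = TRUE)
}

#' Fit the melting sigmoid to a single profile
#'
#' Least-squares fit of [melt_sigmoid()] to one melting profile, with
#' bounds `a > 0`, `b > 0`, `plateau` in `[0, 1)`. Solver failure and
#' degenerate (non-decaying, e.g. constant) profiles yield `valid = FALSE`
#' rather than an error. Tm is the closed-form half-denaturation point,
#' reported only when it lies within the extrapolation window
#' `[min(T) - extrapolation_margin, max(T) + extrapolation_margin]`.
#'
#' @param data Data frame with columns `temperature_c` and `rel_abundance`;
#'   at least 5 distinct temperatures are required.
#' @param extrapolation_margin Degrees C the Tm may lie beyond the measured
#'   grid before being treated as undefined (default 5).
#' @return A `melt_fit` object with elements `a`, `b`, `plateau`, `rss`,
#'   `r_squared`, `tm_c`, `valid`, `n_obs` and the fitting `data`.
#' @examples
#' d <- data.frame(temperature_c = seq(37, 67, length.out = 10))
#' d$rel_abundance <- melt_sigmoid(d$temperature_c, 550, 10, 0.05)
#' fit <- fit_melt_curve(d)
#' glance(fit)
#' @export
fit_melt_curve <- function(data, extrapolation_margin = 5) {
  if (!all(c("temperature_c", "rel_abundance") %in% names(data))) {
    abort("`data` needs columns `temperature_c` and `rel_abundance`",
          class = "tppshift_input_error")
  }
  if (length(unique(data$temperature_c)) < 5) {
    abort("need at least 5 distinct temperatures to fit a melting curve",
          class = "tppshift_input_error")
  }
  y <- data$rel_abundance
  fit <- fit_sigmoid_ls(data$temperature_c, y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (fit$converged && tss > 0) 1 - fit$rss / tss else NA_real_
  window <- range(data$temperature_c) + c(-1, 1) * extrapolation_margin
  tm <- if (fit$converged) compute_tm(fit$a, fit$b, fit$plateau, window) else NA_real_
  structure(
    list(a = fit$a, b = fit$b, plateau = fit$plateau, rss = fit$rss,
         r_squared = r2, tm_c = tm,
         valid = isTRUE(fit$converged) && is.finite(r2),
         n_obs = sum(is.finite(y)), window = window, data = data),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("<melt_fit>",
      if (x$valid) "" else " (not valid)", "\n", sep = "")
  cat(sprintf("  a = %.4g, b = %.4g, plateau = %.4g\n", x$a, x$b, x$plateau))
  cat(sprintf("  rss = %.4g, R^2 = %.4g, Tm = %s C\n", x$rss, x$r_squared,
              if (is.na(x$tm_c)) "undefined" else sprintf("%.2f", x$tm_c)))
  invisible(x)
}

#' @rdname fit_melt_curve
#' @param x,object A `melt_fit`.
#' @param ... Unused.
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "plateau"),
                 estimate = c(x$a, x$b, x$plateau))
}

#' @rdname fit_melt_curve
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, plateau = x$plateau, rss = x$rss,
                 r_squared = x$r_squared, tm_c = x$tm_c, valid = x$valid,
                 n_obs = x$n_obs)
}

#' @rdname fit_melt_curve
#' @method augment melt_fit
#' @export
augment.melt_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  d$.fitted <- melt_sigmoid(d$temperature_c, x$a, x$b, x$plateau)
  d$.resid <- d$rel_abundance - d$.fitted
  d
}

#' @rdname fit_melt_curve
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  grid <- tibble::tibble(
    temperature_c = seq(min(object$data$temperature_c),
                        max(object$data$temperature_c), length.out = 120))
  grid$rel_abundance <- melt_sigmoid(grid$temperature_c, object$a, object$b,
                                     object$plateau)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$temperature_c, .data$rel_abundance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Temperature (°C)", y = "Relative abundance",
                  title = if (is.na(object$tm_c)) "Tm undefined"
                          else sprintf("Tm = %.2f °C", object$tm_c)) +
    ggplot2::theme_minimal()
}

#' Fit melting curves to every profile in a melt table
#'
#' Maps [fit_melt_curve()] over each protein x condition x replicate group
#' and collects one row per fit.
#'
#' @param profiles Long-format melt table (see [read_melt_table()]).
#' @inheritParams fit_melt_curve
#' @return A tibble with columns `protein_id`, `condition`, `replicate`,
#'   `a`, `b`, `plateau`, `rss`, `r_squared`, `tm_c`, `valid`.
#' @export
fit_melt_curves <- function(profiles, extrapolation_margin = 5) {
  check_profile_columns(profiles)
  profiles |>
    dplyr::group_by(.data$protein_id, .data$condition, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(fit_melt_curve(d, extrapolation_margin),
                      tppshift_input_error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(a = NA_real_, b = NA_real_, plateau = NA_real_,
                       rss = NA_real_, r_squared = NA_real_, tm_c = NA_real_,
                       valid = FALSE)
      } else {
        glance(fit)[, c("a", "b", "plateau", "rss", "r_squared", "tm_c",
                        "valid")]
      }
    }) |>
    dplyr::ungroup()
}

#' Melting-curve quality filter
#'
#' Flags fits that qualify as valid sigmoidal melting curves: the fit
#' converged, `r_squared >= r2_min`, `plateau < plateau_max`, and Tm is
#' defined. Thresholds follow common TPP practice and are configurable.
#'
#' @param fits Fit table from [fit_melt_curves()].
#' @param r2_min Minimum coefficient of determination (default 0.8).
#' @param plateau_max Maximum plateau (default 0.3).
#' @param keep If `TRUE`, return only passing rows; otherwise return all
#'   rows with a logical `quality_pass` column added.
#' @return The fit tibble, filtered or flagged.
#' @export
curve_quality_filter <- function(fits, r2_min = 0.8, plateau_max = 0.3,
                                 keep = FALSE) {
  out <- fits |>
    dplyr::mutate(quality_pass =
                    .data$valid &
                    !is.na(.data$r_squared) & .data$r_squared >= r2_min &
                    !is.na(.data$plateau) & .data$plateau < plateau_max &
                    !is.na(.data$tm_c))
  if (keep) dplyr::filter(out, .data$quality_pass) else out
}

#' Per-replicate Tm shifts between treatment and vehicle
#'
#' Computes delta Tm = Tm(treatment) - Tm(vehicle) for every protein and
#' replicate where both condition fits have a defined Tm; other
#' combinations are omitted.
#'
#' @param fits Fit table from [fit_melt_curves()].
#' @param conditions Length-2 character: vehicle label first, treatment
#'   second.
#' @return Tibble of `protein_id`, `replicate`, `tm_vehicle`,
#'   `tm_treatment`, `delta_tm_c`.
#' @export
delta_tm <- function(fits, conditions = c("vehicle", "treatment")) {
  stopifnot(length(conditions) == 2L)
  wide <- fits |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::select("protein_id", "condition", "replicate", "tm_c") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "tm_c")
  for (cn in setdiff(conditions, names(wide))) wide[[cn]] <- NA_real_
  wide |>
    dplyr::transmute(.data$protein_id, .data$replicate,
                     tm_vehicle = .data[[conditions[1]]],
                     tm_treatment = .data[[conditions[2]]],
                     delta_tm_c = .data$tm_treatment - .data$tm_vehicle) |>
    dplyr::filter(!is.na(.data$delta_tm_c))
}

#' Replicate reproducibility of Tm estimates
#'
#' Pearson correlation between replicate-1 and replicate-2 Tm values
#' across proteins, per condition. A measure of assay reproducibility;
#' well-behaved TPP experiments give r in the 0.8-0.95 range.
#'
#' @param fits Fit table from [fit_melt_curves()].
#' @param replicates Which two replicates to correlate (default 1 and 2).
#' @return Tibble of `condition`, `r`, `n_pairs`.
#' @export
replicate_tm_correlation <- function(fits, replicates = c(1L, 2L)) {
  stopifnot(length(replicates) == 2L)
  wide <- fits |>
    dplyr::filter(.data$replicate %in% replicates, !is.na(.data$tm_c)) |>
    dplyr::select("protein_id", "condition", "replicate", "tm_c") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "tm_c",
                       names_prefix = "rep_") |>
    dplyr::filter(!is.na(.data[[paste0("rep_", replicates[1])]]),
                  !is.na(.data[[paste0("rep_", replicates[2])]]))
  out <- wide |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      r = cor(.data[[paste0("rep_", replicates[1])]],
              .data[[paste0("rep_", replicates[2])]]),
      n_pairs = dplyr::n(), .groups = "drop")
  if (nrow(out) == 0 || any(out$n_pairs < 3)) {
    abort("need >= 3 proteins with Tm defined in both replicates per condition",
          class = "tppshift_statistics_error")
  }
  out
}
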