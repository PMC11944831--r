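#' Null-model fit: one curve for both conditions
#'
#' Fits a single melting sigmoid to all points of one protein, pooling
#' both conditions and all replicates — the null hypothesis that treatment
#' does not change thermal stability.
#'
#' @param profiles Melt table rows for one protein (both conditions).
#' @param conditions Length-2 character of expected condition labels.
#' @return List with `a`, `b`, `plateau`, `rss0`, `n_obs`, `converged`.
#' @export
nparc_fit_null <- function(profiles, conditions = c("vehicle", "treatment")) {
  present <- unique(profiles$condition)
  if (!all(conditions %in% present)) {
    abort("null model requires data from both conditions",
          class = "tppshift_input_error")
  }
  if (length(unique(profiles$temperature_c)) < 5) {
    abort("need >= 5 distinct temperatures", class = "tppshift_input_error")
  }
  fit <- fit_sigmoid_ls(profiles$temperature_c, profiles$rel_abundance)
  list(a = fit$a, b = fit$b, plateau = fit$plateau, rss0 = fit$rss,
       n_obs = sum(is.finite(profiles$rel_abundance)),
       converged = fit$converged)
}

#' Alternative-model fit: independent curves per condition
#'
#' Fits one melting sigmoid per condition (replicates pooled within each
#' condition) and reports the summed residual sum of squares. When the
#' pooled null solution is supplied via `null_params` it is added to the
#' start set of each per-condition fit, so the alternative model can never
#' end up worse than the null it nests (beyond solver tolerance).
#'
#' @inheritParams nparc_fit_null
#' @param null_params Optional list with `a`, `b`, `plateau` from
#'   [nparc_fit_null()], used as an additional optimisation start.
#' @return List with per-condition parameter lists (`fits`), `rss1`,
#'   `n_obs`, `converged`.
#' @export
nparc_fit_alternative <- function(profiles,
                                  conditions = c("vehicle", "treatment"),
                                  null_params = NULL) {
  extra <- NULL
  if (!is.null(null_params) && all(is.finite(unlist(
    null_params[c("a", "b", "plateau")])))) {
    extra <- list(list(a = null_params$a, b = null_params$b,
                       plateau = min(max(null_params$plateau, 0), 0.999)))
  }
  fits <- lapply(conditions, function(cond) {
    d <- profiles[profiles$condition == cond, ]
    if (length(unique(d$temperature_c)) < 5) {
      abort(sprintf("condition %s: need >= 5 distinct temperatures", cond),
            class = "tppshift_input_error")
    }
    fit_sigmoid_ls(d$temperature_c, d$rel_abundance, extra_starts = extra)
  })
  names(fits) <- conditions
  conv <- all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  list(fits = fits,
       rss1 = if (conv) sum(vapply(fits, `[[`, numeric(1), "rss")) else NA_real_,
       n_obs = sum(is.finite(profiles$rel_abundance[
         profiles$condition %in% conditions])),
       converged = conv)
}

#' F-statistic and p-value for the null vs alternative curve comparison
#'
#' \deqn{F = \frac{(RSS_0 - RSS_1)/(p_1 - p_0)}{RSS_1/(n - p_1)}}
#' with `p` the upper tail of `F(p1 - p0, n - p1)`. `F` is clamped at 0
#' when `rss0 < rss1` within solver tolerance (the models are nested, so
#' negative differences are numerical noise). A degenerate exact
#' alternative fit (`rss1 = 0`) gives a floored p-value of 1e-300 with a
#' warning instead of NaN.
#'
#' @param rss0,rss1 Residual sums of squares of the null and alternative
#'   fits (vectorised).
#' @param n_obs Number of observations per protein.
#' @param p0,p1 Parameter counts of the null (3) and alternative (6)
#'   models.
#' @return Tibble of `f_stat`, `df1`, `df2`, `p_value`.
#' @examples
#' nparc_f_test(rss0 = 2, rss1 = 1, n_obs = 40)  # F = 11.33, p ~ 2.3e-05
#' @export
nparc_f_test <- function(rss0, rss1, n_obs, p0 = 3, p1 = 6) {
  if (any(n_obs <= p1)) {
    abort("n_obs must exceed the alternative parameter count p1",
          class = "tppshift_input_error")
  }
  df1 <- p1 - p0
  df2 <- n_obs - p1
  zero_rss1 <- rss1 <= 0
  if (any(zero_rss1)) {
    warn("rss1 = 0 for some proteins; their p-values are floored at 1e-300")
  }
  f_stat <- ifelse(zero_rss1, Inf,
                   pmax(0, (rss0 - rss1) / df1) / (rss1 / df2))
  p <- ifelse(zero_rss1, 1e-300,
              pf(f_stat, df1, df2, lower.tail = FALSE))
  tibble::tibble(f_stat = f_stat, df1 = df1, df2 = df2,
                 p_value = pmax(p, 1e-300))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across all tested proteins,
#' with input validation. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order-preserving, in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]", class = "tppshift_input_error")
  }
  p.adjust(p, method = "BH")
}

## Quantile-matched scaled chi-square: x ~ scale * chisq(df). The
## interquartile ratio q75/q25 depends only on df; the median then pins the
## scale. Quartiles are robust to an upper tail of true shifters, so the
## estimate reflects the null bulk.
match_scaled_chisq <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 20) return(NULL)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (q[1] <= 0 || q[3] <= q[1]) return(NULL)
  ratio <- q[3] / q[1]
  root <- tryCatch(
    uniroot(function(d) qchisq(0.75, d) / qchisq(0.25, d) - ratio,
            interval = c(0.05, 1000))$root,
    error = function(e) NULL)
  if (is.null(root)) return(NULL)
  list(df = root, scale = q[2] / qchisq(0.5, root))
}

#' Proteome-wide NPARC test for treatment-induced melting shifts
#'
#' For every protein, fits the pooled null model and the per-condition
#' alternative model, forms the RSS-based F-statistic, converts it to a
#' p-value, adjusts across proteins by Benjamini-Hochberg and assigns hit
#' tiers.
#'
#' Two p-value modes are available. `"theoretical"` uses the nominal
#' degrees of freedom `(p1 - p0, n - p1)`. `"empirical"` (the default)
#' moment-matches scaled chi-square distributions to the observed ensemble
#' of RSS differences and residual RSS by robust quantile matching, which
#' restores near-uniform null p-values when residuals deviate from the
#' i.i.d.-Gaussian ideal (as they do under the multiplicative noise typical
#' of relative-abundance data, where the theoretical F-test is
#' conservative). With fewer than 20 testable proteins the empirical mode
#' falls back to theoretical with a warning.
#'
#' @param profiles Long-format melt table covering both conditions.
#' @param conditions Length-2 character: vehicle label first.
#' @param df_mode `"empirical"` or `"theoretical"`.
#' @param p0,p1 Model parameter counts (3 and 6).
#' @param alpha,marked_alpha,adj_alpha Tier thresholds passed to
#'   [classify_hits()].
#' @return A `tpp_nparc` tibble: `protein_id`, `rss0`, `rss1`, `n_obs`,
#'   `df1`, `df2`, `f_stat`, `p_value`, `p_adjusted`, `tier`, `testable`.
#'   Untestable proteins (failed fits, too few points, missing condition)
#'   carry NA statistics and are excluded before the BH adjustment, so the
#'   multiplicity correction runs over actually tested hypotheses.
#' @export
nparc_test <- function(profiles, conditions = c("vehicle", "treatment"),
                       df_mode = c("empirical", "theoretical"),
                       p0 = 3, p1 = 6,
                       alpha = 0.05, marked_alpha = 0.01, adj_alpha = 0.1) {
  df_mode <- match.arg(df_mode)
  check_profile_columns(profiles)

  per_protein <- profiles |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      res <- tryCatch({
        null <- nparc_fit_null(d, conditions)
        alt <- nparc_fit_alternative(d, conditions, null_params = null)
        if (!null$converged || !alt$converged || null$n_obs <= p1) {
          NULL
        } else {
          tibble::tibble(rss0 = null$rss0, rss1 = alt$rss1,
                         n_obs = null$n_obs, testable = TRUE)
        }
      }, tppshift_input_error = function(e) NULL)
      res %||% tibble::tibble(rss0 = NA_real_, rss1 = NA_real_,
                              n_obs = NA_integer_, testable = FALSE)
    }) |>
    dplyr::ungroup()

  tested <- dplyr::filter(per_protein, .data$testable)
  out <- per_protein |>
    dplyr::mutate(f_stat = NA_real_, df1 = NA_real_, df2 = NA_real_,
                  p_value = NA_real_, p_adjusted = NA_real_)

  emp <- NULL
  if (nrow(tested) > 0) {
    if (df_mode == "empirical") {
      delta <- pmax(tested$rss0 - tested$rss1, 0)
      m1 <- match_scaled_chisq(delta)
      m2 <- match_scaled_chisq(tested$rss1)
      if (is.null(m1) || is.null(m2)) {
        warn("too few proteins for empirical df estimation; using theoretical df")
        df_mode <- "theoretical"
      } else {
        emp <- list(d1 = m1$df, d2 = m2$df, s1 = m1$scale, s2 = m2$scale)
      }
    }
    if (df_mode == "empirical") {
      delta <- pmax(tested$rss0 - tested$rss1, 0)
      zero1 <- tested$rss1 <= 0
      f_emp <- ifelse(zero1, Inf,
                      (delta / (emp$s1 * emp$d1)) /
                        (tested$rss1 / (emp$s2 * emp$d2)))
      p <- ifelse(zero1, 1e-300,
                  pf(f_emp, emp$d1, emp$d2, lower.tail = FALSE))
      ftab <- tibble::tibble(f_stat = f_emp, df1 = emp$d1, df2 = emp$d2,
                             p_value = pmax(p, 1e-300))
    } else {
      ftab <- nparc_f_test(tested$rss0, tested$rss1, tested$n_obs, p0, p1)
    }
    ftab$p_adjusted <- bh_adjust(ftab$p_value)
    idx <- match(tested$protein_id, out$protein_id)
    out$f_stat[idx] <- ftab$f_stat
    out$df1[idx] <- ftab$df1
    out$df2[idx] <- ftab$df2
    out$p_value[idx] <- ftab$p_value
    out$p_adjusted[idx] <- ftab$p_adjusted
  }

  out <- classify_hits(out, alpha = alpha, marked_alpha = marked_alpha,
                       adj_alpha = adj_alpha)
  structure(out, class = c("tpp_nparc", class(out)),
            df_mode = df_mode, empirical_df = emp)
}

#' Assign hit tiers from nominal and adjusted p-values
#'
#' Three nested evidence tiers: `significant` (p < `alpha`), `marked`
#' (p < `marked_alpha`, a subset of significant) and `prime`
#' (adjusted p < `adj_alpha`, computed independently of the nominal
#' tiers). The `tier` column records the strongest applicable label.
#'
#' @param results Data frame with `p_value` and `p_adjusted` columns.
#' @param alpha Nominal significance threshold (default 0.05).
#' @param marked_alpha Stricter nominal threshold (default 0.01).
#' @param adj_alpha Adjusted-p threshold for prime targets (default 0.1).
#' @return `results` with a `tier` column
#'   (`prime` > `marked` > `significant` > `none`).
#' @seealso [hit_summary()]
#' @export
classify_hits <- function(results, alpha = 0.05, marked_alpha = 0.01,
                          adj_alpha = 0.1) {
  p <- results$p_value
  padj <- results$p_adjusted
  tier <- rep("none", nrow(results))
  tier[!is.na(p) & p < alpha] <- "significant"
  tier[!is.na(p) & p < marked_alpha] <- "marked"
  tier[!is.na(padj) & padj < adj_alpha] <- "prime"
  results$tier <- factor(tier, levels = c("prime", "marked", "significant",
                                          "none"))
  results
}

#' Hit-tier counts
#'
#' @param results Output of [nparc_test()] (or any table with `p_value`,
#'   `p_adjusted` and optionally `testable`).
#' @inheritParams classify_hits
#' @return One-row tibble: `n_proteins`, `n_tested`, `n_significant`
#'   (p < `alpha`), `n_marked` (p < `marked_alpha`), `n_prime`
#'   (adjusted p < `adj_alpha`).
#' @export
hit_summary <- function(results, alpha = 0.05, marked_alpha = 0.01,
                        adj_alpha = 0.1) {
  p <- results$p_value
  padj <- results$p_adjusted
  tibble::tibble(
    n_proteins = nrow(results),
    n_tested = if ("testable" %in% names(results)) sum(results$testable)
               else sum(!is.na(p)),
    n_significant = sum(p < alpha, na.rm = TRUE),
    n_marked = sum(p < marked_alpha, na.rm = TRUE),
    n_prime = sum(padj < adj_alpha, na.rm = TRUE))
}

#' Summary of an NPARC result table
#'
#' @param x A `tpp_nparc` result.
#' @param ... Unused.
#' @return One-row tibble of hit-tier counts plus the df mode used.
#' @method glance tpp_nparc
#' @export
glance.tpp_nparc <- function(x, ...) {
  dplyr::bind_cols(hit_summary(x),
                   tibble::tibble(df_mode = attr(x, "df_mode")))
}

#' P-value histogram for an NPARC result
#'
#' @param object A `tpp_nparc` result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tpp_nparc
#' @export
autoplot.tpp_nparc <- function(object, bins = 30, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$testable)
  ggplot2::ggplot(d, ggplot2::aes(.data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey70",
                            colour = "grey30") +
    ggplot2::labs(x = "NPARC p-value", y = "Proteins") +
    ggplot2::theme_minimal()
}
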