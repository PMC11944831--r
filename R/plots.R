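#' Plot melting curves for selected proteins
#'
#' Observed relative abundances by temperature, coloured by condition,
#' faceted by protein, with fitted sigmoids overlaid when a fit table is
#' supplied.
#'
#' @param profiles Long-format melt table.
#' @param fits Optional fit table from [fit_melt_curves()].
#' @param proteins Protein ids to show (default: first 4).
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(profiles, fits = NULL, proteins = NULL) {
  check_profile_columns(profiles)
  proteins <- proteins %||% head(unique(profiles$protein_id), 4)
  d <- dplyr::filter(profiles, .data$protein_id %in% proteins)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$temperature_c,
                                       .data$rel_abundance,
                                       colour = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        alpha = 0.8) +
    ggplot2::facet_wrap(~protein_id) +
    ggplot2::labs(x = "Temperature (°C)", y = "Relative abundance",
                  colour = "Condition", shape = "Replicate") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- fits |>
      dplyr::filter(.data$protein_id %in% proteins, .data$valid) |>
      dplyr::group_by(.data$protein_id, .data$condition, .data$replicate) |>
      dplyr::reframe(temperature_c = seq(min(d$temperature_c),
                                         max(d$temperature_c),
                                         length.out = 80),
                     rel_abundance = melt_sigmoid(.data$temperature_c,
                                                  .data$a, .data$b,
                                                  .data$plateau))
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(group = interaction(
                                  .data$condition, .data$replicate)),
                                linewidth = 0.4)
  }
  p
}
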