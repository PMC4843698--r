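#' Plot fitted richness-response lines
#'
#' Draws the pooled (black) and per-study (grey) fitted lines of a mixed
#' model over the richness gradient, one line type per treatment, on the
#' back-transformed response scale. Requires ggplot2.
#'
#' @param fit a converged [reml_fit()].
#' @param n_grid number of richness grid points.
#' @return a ggplot object.
#' @export
plot_fitted_lines <- function(fit, n_grid = 50) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fitted_lines needs the ggplot2 package", call. = FALSE)
  }
  rng <- range(fit$design$index$sown_richness)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid))
  pooled <- fitted_lines(fit, richness = grid, level = "pooled")
  per_study <- fitted_lines(fit, richness = grid, level = "per_study")
  ggplot2::ggplot(mapping = ggplot2::aes(
    x = .data$sown_richness, y = .data$fit_response,
    linetype = .data$treatment)) +
    ggplot2::geom_line(data = per_study,
                       ggplot2::aes(group = interaction(.data$study_id,
                                                        .data$treatment)),
                       colour = "grey70") +
    ggplot2::geom_line(data = pooled, colour = "black", linewidth = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Sown species richness",
                  y = paste0(fit$spec$response, " (back-transformed)")) +
    ggplot2::theme_minimal()
}

# make R CMD check quiet about ggplot2's tidy-eval pronoun
utils::globalVariables(".data")
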