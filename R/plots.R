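condition_colours <- function() {
  c(VSL = "#1b7837", IS = "#2166ac", ID = "#b2182b")
}

#' Plot mean number-line mappings with central-tendency fits
#'
#' Mean response per numerosity for each condition, overlaid with the fitted
#' posterior-mean mapping from the report's Bayesian fits and the identity
#' line.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_mapping <- function(report) {
  obs <- do.call(rbind, lapply(report$bayes, function(b) {
    cbind(b$predicted, condition = b$condition)
  }))
  ggplot2::ggplot(obs, ggplot2::aes(x = numerosity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = mean_response,
                                     colour = condition), size = 1.4) +
    ggplot2::geom_line(ggplot2::aes(y = predicted,
                                    colour = condition)) +
    ggplot2::scale_colour_manual(values = condition_colours()) +
    ggplot2::labs(x = "Numerosity", y = "Mean number-line response",
                  colour = "Condition",
                  title = "Number-line mapping and central-tendency fits") +
    ggplot2::theme_minimal()
}

#' Plot response SD against numerosity with the pooled power fit
#'
#' @param report A `study_report`.
#' @param clean Cleaned trial data frame the report was computed from.
#' @return A ggplot object.
#' @export
plot_sd_scaling <- function(report, clean) {
  noise <- compute_noise_summary(clean)
  tab <- noise$sd_by_numerosity
  fit <- report$sd_power_pooled
  curve <- data.frame(numerosity = seq(min(tab$numerosity), max(tab$numerosity),
                                       length.out = 100))
  curve$sd <- fit$scale * curve$numerosity^fit$exponent
  ggplot2::ggplot(tab, ggplot2::aes(x = numerosity, y = sd)) +
    ggplot2::geom_point(ggplot2::aes(colour = condition), size = 1.2) +
    ggplot2::geom_line(data = curve, colour = "black", linetype = "dashed") +
    ggplot2::scale_colour_manual(values = condition_colours()) +
    ggplot2::labs(x = "Numerosity", y = "Response SD", colour = "Condition",
                  title = sprintf("Precision scaling (pooled exponent %.2f)",
                                  fit$exponent)) +
    ggplot2::theme_minimal()
}

#' Plot non-linearity against internal noise with the model curve
#'
#' Subject x condition points (non-linearity index `1 - exponent` against
#' internal noise) together with the ideal-observer prediction from
#' [nonlinearity_vs_noise_curve()].
#'
#' @param report A `study_report`.
#' @param curve Optional precomputed model curve; by default computed with a
#'   17-dot prior SD and the report's seed.
#' @return A ggplot object.
#' @export
plot_nonlinearity_noise <- function(report, curve = NULL) {
  if (is.null(curve)) {
    curve <- nonlinearity_vs_noise_curve(prior_sd = 17, seed = report$seed)
  }
  pts <- report$subject_fits
  ggplot2::ggplot(pts, ggplot2::aes(x = internal_noise,
                                    y = 1 - exponent)) +
    ggplot2::geom_point(ggplot2::aes(colour = condition), size = 1.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = internal_noise,
                                    y = 1 - exponent),
                       colour = "grey40", inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = condition_colours()) +
    ggplot2::labs(x = "Internal noise (SD of response/numerosity)",
                  y = "Non-linearity (1 - exponent)", colour = "Condition",
                  title = "Central-tendency prediction vs simulated subjects") +
    ggplot2::theme_minimal()
}

save_report_plots <- function(report, clean, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(file.path(dir, "mapping.png"), plot_mapping(report),
                  width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(dir, "sd_scaling.png"),
                  plot_sd_scaling(report, clean),
                  width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(dir, "nonlinearity_noise.png"),
                  plot_nonlinearity_noise(report),
                  width = 6, height = 4, dpi = 150)
  invisible(dir)
}
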