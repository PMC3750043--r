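# Optional presentation-layer plotting (ggplot2 is suggested, not required).

#' Plot experimental mixture data, band, predictions and contributions
#'
#' Reproduces the standard mixture-figure layout: experimental mean +/- SD
#' points, the fitted sigmoid with its confidence band, the model prediction
#' lines and the per-chemical contribution curves, on a log10 concentration
#' axis.
#'
#' @param mix_data experimental mixture response dataset (optional).
#' @param band a `confidence_band` (optional).
#' @param predictions named list of `prediction_curve`s (optional).
#' @param contributions list of `contribution_curve`s (optional).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_mixture_analysis <- function(mix_data = NULL, band = NULL,
                                  predictions = NULL, contributions = NULL,
                                  title = "Mixture effect prediction") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    mh_stop("ggplot2 is required for plotting", "mixhill_input_error")
  gg <- ggplot2::ggplot() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Total mixture concentration (uM)",
                  y = "Effect (% of control)", title = title,
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    b <- tibble::as_tibble(band)
    gg <- gg +
      ggplot2::geom_ribbon(
        data = b,
        ggplot2::aes(x = .data$concentration_uM, ymin = .data$lower,
                     ymax = .data$upper),
        fill = "grey80", alpha = 0.6) +
      ggplot2::geom_line(
        data = b,
        ggplot2::aes(x = .data$concentration_uM, y = .data$fit),
        colour = "black")
  }
  if (!is.null(mix_data)) {
    d <- mix_data[mix_data$concentration_uM > 0, ]
    agg <- dplyr::summarise(
      dplyr::group_by(d, .data$concentration_uM),
      mean = mean(.data$response_pct), sd = stats::sd(.data$response_pct),
      .groups = "drop")
    gg <- gg +
      ggplot2::geom_pointrange(
        data = agg,
        ggplot2::aes(x = .data$concentration_uM, y = .data$mean,
                     ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd))
  }
  if (!is.null(predictions) && length(predictions) > 0) {
    pd <- dplyr::bind_rows(lapply(names(predictions), function(m) {
      tibble::tibble(model = m,
                     concentration_uM = predictions[[m]]$concentration_uM,
                     effect_pct = predictions[[m]]$effect_pct)
    }))
    gg <- gg + ggplot2::geom_line(
      data = pd,
      ggplot2::aes(x = .data$concentration_uM, y = .data$effect_pct,
                   colour = .data$model))
  }
  if (!is.null(contributions) && length(contributions) > 0) {
    cd <- dplyr::bind_rows(contributions)
    gg <- gg + ggplot2::geom_line(
      data = cd,
      ggplot2::aes(x = .data$concentration_uM, y = .data$effect_pct,
                   group = .data$chemical),
      linetype = "dashed", colour = "grey40")
  }
  gg
}
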