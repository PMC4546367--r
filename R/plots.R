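#' Plot a fitted growth curve
#'
#' Observations, the fitted sigmoid and the inflection point (dashed
#' guides) on a weight-by-age canvas.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  t_max <- max(object$data$age_days)
  grid <- tibble::tibble(age_days = seq(0, t_max, length.out = 400))
  grid$weight_kg <- predict(object, grid)
  ip <- suppressWarnings(inflection_point(object))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$age_days, .data$weight_kg)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = ip$t_star_days, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = ip$w_star_kg, linetype = "dashed") +
    ggplot2::labs(
      x = "Age (days)", y = "Weight (kg)",
      title = sprintf("%s fit (R² = %.4f)", object$model, object$r2),
      subtitle = sprintf(
        "inflection: %.1f d, %.1f kg; max daily gain %.1f g/d",
        ip$t_star_days, ip$w_star_kg, ip$g_max_g_day)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranked growth models
#'
#' Overlays the fitted curves of all models in a [compare_models()] result
#' over the observations.
#'
#' @param object A `growth_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_comparison <- function(object, ...) {
  fits <- attr(object, "fits")
  fits <- fits[!vapply(fits, is.null, TRUE)]
  obs <- fits[[1L]]$data
  t_max <- max(obs$age_days)
  grid <- purrr::map(fits, function(f) {
    g <- tibble::tibble(age_days = seq(0, t_max, length.out = 400))
    g$weight_kg <- predict(f, g)
    g$model <- f$model
    g
  })
  ggplot2::ggplot(obs, ggplot2::aes(.data$age_days, .data$weight_kg)) +
    ggplot2::geom_point(size = 2, colour = "grey30") +
    ggplot2::geom_line(data = dplyr::bind_rows(grid),
                       ggplot2::aes(colour = .data$model)) +
    ggplot2::labs(x = "Age (days)", y = "Weight (kg)", colour = "model") +
    ggplot2::theme_minimal()
}

#' Saturation-curve plot
#'
#' @param saturation Output of [saturation_curve()].
#' @return A ggplot.
#' @export
plot_saturation <- function(saturation) {
  ggplot2::ggplot(saturation, ggplot2::aes(.data$depth,
                                           .data$mean_detected)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Subsampled tags", y = "Distinct genes detected") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a DEG table
#'
#' @param degs Output of [call_degs()].
#' @return A ggplot.
#' @export
plot_volcano <- function(degs) {
  ggplot2::ggplot(degs, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                     colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Replicate-correlation tile plot
#'
#' @param corr Output of [replicate_correlation()].
#' @return A ggplot.
#' @export
plot_replicate_correlation <- function(corr) {
  both <- dplyr::bind_rows(
    corr,
    dplyr::rename(corr, library_a = "library_b", library_b = "library_a")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$library_a, .data$library_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
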