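#' Plot JND trajectories over time
#'
#' Per-treatment trajectories of a matching response (default: chromatic
#' JND) with a linear trend per treatment. The horizontal reference at 1 JND
#' marks the conventional discrimination threshold: values below it are
#' indistinguishable from the background to the modelled receiver.
#'
#' @param records A record tibble.
#' @param response Response column (bare name or string).
#' @param threshold Reference level drawn as a dashed line (NULL omits it).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(records, response = "chromatic_jnd",
                              threshold = 1) {
  records <- tibble::as_tibble(records)
  resp <- resolve_column(rlang::enquo(response), records)
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$time_min, y = .data[[resp]],
                                    colour = .data$treatment)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.7) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "time (min)", y = resp) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @method autoplot energy_spectrum
#' @export
autoplot.energy_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale_px, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial scale (px)", y = "pattern energy (SD)") +
    ggplot2::theme_minimal()
}

#' Compare two pattern-energy spectra
#'
#' Overlays the animal and background spectra and marks the background's
#' dominant spatial scale, the scale at which pattern matching is judged.
#'
#' @param animal_spectrum,background_spectrum [energy_spectrum()] tibbles.
#' @return A ggplot object.
#' @export
plot_spectrum_pair <- function(animal_spectrum, background_spectrum) {
  check_spectrum(animal_spectrum); check_spectrum(background_spectrum)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(animal_spectrum), region = "animal"),
    dplyr::mutate(tibble::as_tibble(background_spectrum), region = "background"))
  dom <- dominant_scale(background_spectrum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale_px, y = .data$energy,
                                   colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = dom, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial scale (px)", y = "pattern energy (SD)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  st <- slope_table(object)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$treatment, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower_cl,
                                          ymax = .data$upper_cl)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s trend (per minute)", object$response)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
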