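#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coherence spectrum
#'
#' Channel-averaged phase coherence against frequency.
#'
#' @param object A `coherence_spectrum` tibble.
#' @param f_max Upper frequency limit of the plot, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coherence_spectrum
#' @export
autoplot.coherence_spectrum <- function(object, f_max = 15, ...) {
  avg <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(object, .data$frequency <= f_max, .data$frequency > 0),
                    .data$frequency),
    coherence = mean(.data$coherence), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$frequency, .data$coherence)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Phase coherence") +
    ggplot2::theme_minimal()
}

#' Plot observed coherence against its shuffle chance level
#'
#' @param object A `coherence_null` tibble (channel-averaged form).
#' @param f_max Upper frequency limit, Hz.
#' @param alpha Significance threshold for the FDR-adjusted p marks.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coherence_null
#' @export
autoplot.coherence_null <- function(object, f_max = 15, alpha = 0.05, ...) {
  d <- dplyr::filter(object, .data$frequency <= f_max, .data$frequency > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$frequency, .data$observed)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::geom_line(ggplot2::aes(y = .data$chance), linetype = "dashed") +
    ggplot2::geom_point(data = dplyr::filter(d, .data$p_fdr < alpha),
                        color = "#c23b22", size = 1) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Phase coherence",
                  caption = "dashed: chance level; points: FDR-significant bins") +
    ggplot2::theme_minimal()
}

#' Plot TRF kernels
#'
#' Channel-averaged kernels per predictor stream.
#'
#' @param object An `echo_trf`.
#' @param rate Analysis rate used to label the lag axis, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot echo_trf
#' @export
autoplot.echo_trf <- function(object, rate = 100, ...) {
  d <- tidy(object)
  avg <- dplyr::summarise(dplyr::group_by(d, .data$lag_s, .data$stream),
                          weight = mean(.data$weight), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$lag_s, .data$weight,
                                    color = .data$stream)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (s)", y = "TRF weight", color = "Stream") +
    ggplot2::theme_minimal()
}

#' Plot a modulation spectrum
#'
#' @param object A `modulation_spectrum` tibble.
#' @param echo_delay_s Optional echo delay; marks the echo-related
#'   frequencies with dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot modulation_spectrum
#' @export
autoplot.modulation_spectrum <- function(object, echo_delay_s = NULL, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$amplitude)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "Modulation frequency (Hz)", y = "Normalized amplitude") +
    ggplot2::theme_minimal()
  if (!is.null(echo_delay_s)) {
    ef <- echo_related_frequencies(echo_delay_s, max(object$frequency))
    g <- g + ggplot2::geom_vline(xintercept = ef, linetype = "dashed",
                                 color = "grey50")
  }
  g
}

#' Bar plot of TRF model predictive power
#'
#' @param trf_power Tibble with columns `kind`, `power`, and optionally
#'   `participant` (plotted as dots).
#' @return A ggplot object.
#' @export
plot_predictive_power <- function(trf_power) {
  avg <- dplyr::summarise(dplyr::group_by(trf_power, .data$kind),
                          power = mean(.data$power), .groups = "drop")
  g <- ggplot2::ggplot(avg, ggplot2::aes(.data$kind, .data$power)) +
    ggplot2::geom_col(fill = "#88a8c4", width = 0.6) +
    ggplot2::labs(x = NULL, y = "Predictive power") +
    ggplot2::theme_minimal()
  if ("participant" %in% names(trf_power)) {
    g <- g + ggplot2::geom_point(data = trf_power, color = "grey30",
                                 alpha = 0.7,
                                 position = ggplot2::position_jitter(width = 0.08, seed = 1))
  }
  g
}
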