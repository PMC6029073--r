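#' Plot divergence against perturbation fraction
#'
#' Draws the mean replicate divergence per fraction with a ribbon of
#' plus/minus three standard errors, one colour per parameter group, and
#' an optional horizontal reference line at the wild-type model fit.
#'
#' @param object A `"hog_sweep"` tibble (or several row-bound together).
#' @param wt_reference Optional numeric: mean wild-type-to-model
#'   divergence drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hog_sweep <- function(object, wt_reference = NULL, ...) {
  summ <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$parameter_group, .data$fraction) |>
    dplyr::summarise(mean_kl = mean(.data$kl_nats),
                     se_kl = stats::sd(.data$kl_nats) / sqrt(dplyr::n()),
                     .groups = "drop")
  gg <- ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$fraction, y = .data$mean_kl,
    colour = .data$parameter_group, fill = .data$parameter_group)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_kl - 3 * .data$se_kl,
      ymax = .data$mean_kl + 3 * .data$se_kl), alpha = 0.2,
      colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "parameter scale (fraction of original value)",
                  y = "KL divergence (nats)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
  if (!is.null(wt_reference)) {
    gg <- gg + ggplot2::geom_hline(yintercept = wt_reference,
                                   linetype = "dashed")
  }
  gg
}

#' Plot a simulated population histogram
#'
#' @param object A `"hog_sim"` tibble from [simulate_population()].
#' @param log10_offset Offset added before the log10 transform.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hog_sim <- function(object, log10_offset = exp(2.5), ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = log10(.data$protein + log10_offset))) +
    ggplot2::geom_histogram(bins = 80, fill = "steelblue",
                            colour = NA) +
    ggplot2::labs(x = "log10(reporter protein + basal)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Overlaid reporter histograms for a set of flow samples
#'
#' @param samples Flow-sample tibble.
#' @param bins Histogram bins.
#' @return A ggplot object faceted by strain, coloured by condition.
#' @export
plot_flow_histograms <- function(samples, bins = 80) {
  validate_flow_samples(samples)
  long <- samples |>
    dplyr::mutate(values = .data$intensities) |>
    tidyr::unnest_longer("values") |>
    dplyr::select(-"intensities")
  ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$values),
                                     fill = .data$condition)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~ .data$strain) +
    ggplot2::labs(x = "log10 fluorescence (a.u.)", y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
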