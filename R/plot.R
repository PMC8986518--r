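#' Plot a spectrum on a log-period axis
#'
#' @param object An `ecots_spectrum` tibble.
#' @param bands Optional [surrogate_bands()] tibble; draws the upper
#'   null band for the first series.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ecots_spectrum <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$period, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "timescale (period)",
                  y = if (isTRUE(attr(object, "normalized")))
                    "normalized power" else "power")
  if (!is.null(bands))
    p <- p + ggplot2::geom_line(
      data = bands, ggplot2::aes(y = .data$spec1_upper), linetype = 2)
  p
}

#' Plot a cospectrum with optional surrogate band envelope
#'
#' @param object An `ecots_cospectrum` tibble.
#' @param bands Optional [surrogate_bands()] tibble with `co_lower` and
#'   `co_upper` columns.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ecots_cospectrum <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$period, y = .data$cospectrum)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "timescale (period)", y = "normalized cospectrum")
  if (!is.null(bands))
    p <- p +
      ggplot2::geom_line(data = bands, ggplot2::aes(y = .data$co_lower), linetype = 2) +
      ggplot2::geom_line(data = bands, ggplot2::aes(y = .data$co_upper), linetype = 2)
  p
}

#' Plot an extinction-risk sweep
#'
#' Extinction probability of each species against noise spectral slope,
#' one panel line pair per competition intensity. The x axis runs blue
#' (+2) to red (-2) to match the sweep direction.
#'
#' @param object An `ecots_sweep` tibble from [extinction_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ecots_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("p_ext_native", "p_ext_invader"),
                              names_to = "species", values_to = "p_ext")
  long$species <- ifelse(long$species == "p_ext_native", "native", "invader")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$slope, y = .data$p_ext,
                                     color = factor(.data$alpha),
                                     linetype = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "noise spectral slope (blue to red)",
                  y = "extinction probability", color = "alpha")
}

#' Plot a mean-field wavelet power surface
#'
#' Time-frequency heat map of station-averaged wavelet power with the
#' cone of influence drawn as a dashed curve; cells of a significance
#' mask can be outlined.
#'
#' @param object An `ecots_meanfield` (or `ecots_cwt`) object.
#' @param mask Optional logical matrix of the same shape (e.g. from
#'   [tandem_surrogate_mask()]) marking significant cells.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ecots_meanfield <- function(object, mask = NULL, ...) {
  tt <- if (!is.null(object$years)) object$years else object$time
  long <- tidyr::expand_grid(time = tt, period = object$periods)
  long$power <- as.vector(t(object$power))
  if (!is.null(mask)) long$significant <- as.vector(t(mask))
  coi <- tibble(time = tt, coi = object$coi_period)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_line(data = coi, ggplot2::aes(y = pmax(.data$coi, min(object$periods))),
                       linetype = 2, color = "white") +
    ggplot2::labs(x = "time", y = "period", fill = "power")
  if (!is.null(mask))
    p <- p + ggplot2::geom_point(
      data = long[long$significant, ], size = 0.3, color = "black")
  p
}

#' @export
autoplot.ecots_cwt <- autoplot.ecots_meanfield

#' Histogram panel of era-wise spectral exponents
#'
#' @param era_tab Output of [era_exponents()].
#' @param bins Histogram bins; default 30.
#' @return A ggplot object, one facet per era, with the era mean marked.
#' @export
plot_era_histograms <- function(era_tab, bins = 30) {
  means <- dplyr::summarise(dplyr::group_by(era_tab, .data$era),
                            m = mean(.data$exponent))
  ggplot2::ggplot(era_tab, ggplot2::aes(x = .data$exponent)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(data = means, ggplot2::aes(xintercept = .data$m),
                        color = "red") +
    ggplot2::facet_wrap(~era) +
    ggplot2::labs(x = "spectral exponent", y = "stations")
}
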