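#' Zero-phase seasonal band-stop filter
#'
#' Attenuates cyclic components with periods inside `stop_period` (by
#' default 9-15 sampling units, bracketing the annual cycle in monthly
#' data) while passing longer and shorter timescales essentially
#' unchanged. The filter is a Chebyshev type II band-stop applied
#' forward and backward (`signal::filtfilt`), so retained components are
#' not phase-shifted. The design meets: a pure 12-month sinusoid is
#' attenuated by more than 20 dB; pure 6-month and 36-month sinusoids
#' pass with less than 5% amplitude change.
#'
#' @param data Data frame with the series to filter.
#' @param value Column to filter (tidy-eval).
#' @param stop_period Length-2 numeric, the stop band in period units.
#' @param dt Sampling interval in the same units.
#' @param order Filter order (per pass); default 4.
#' @param Rs Stopband ripple in dB (per pass); default 20.
#' @return The input data with an added `filtered` column.
#' @export
bandstop_filter <- function(data, value, stop_period = c(9, 15), dt = 1,
                            order = 4, Rs = 20) {
  x <- pull_num(data, {{ value }})
  n <- length(x)
  stop_period <- sort(as.numeric(stop_period))
  if (length(stop_period) != 2 || any(stop_period <= 0))
    abort("stop_period must be two positive periods")
  # band edges as fractions of the Nyquist frequency
  W <- sort(2 * dt / stop_period)
  if (W[2] >= 1 || W[1] <= 0)
    abort("stop band outside representable frequencies")
  if (n < 4 * max(stop_period) / dt)
    abort("series too short for stable band-stop filtering (need n >= 4 x longest stop period)")
  flt <- signal::cheby2(order, Rs, W, type = "stop")
  mu <- mean(x)
  y <- signal::filtfilt(flt, x - mu) + mu
  dplyr::mutate(data, filtered = y)
}
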