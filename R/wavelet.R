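#' Generalized Morse wavelet machinery
#'
#' The analytic generalized Morse wavelet is defined in the frequency
#' domain as psi_hat(omega) = a omega^beta exp(-omega^gamma) for
#' omega > 0 (zero otherwise), with symmetry parameter gamma and
#' beta = time_bandwidth / gamma, normalized so the peak value is 2.
#' Its peak radian frequency is omega_p = (beta/gamma)^(1/gamma); scale
#' s shifts the peak to omega_p / s.
#'
#' @noRd
morse_peak_freq <- function(gamma, beta) (beta / gamma)^(1 / gamma)

morse_hat <- function(omega, gamma, beta) {
  a <- 2 / (morse_peak_freq(gamma, beta)^beta *
              exp(-morse_peak_freq(gamma, beta)^gamma))
  out <- numeric(length(omega))
  pos <- omega > 0
  out[pos] <- a * omega[pos]^beta * exp(-omega[pos]^gamma)
  out
}

# one-sided e-folding half-width of the unit-scale wavelet envelope (in
# the wavelet's own time units); scales linearly with s
morse_efold <- function(gamma, beta) {
  L <- 8192
  dw <- 0.01
  w <- (0:(L - 1)) * dw
  ph <- morse_hat(w, gamma, beta)
  psi <- fft(ph, inverse = TRUE) * dw / (2 * pi)
  env <- Mod(psi)
  tgrid <- (0:(L - 1)) * (2 * pi / (L * dw))
  peak <- max(env)
  idx <- which(env < peak / exp(1))
  tgrid[idx[1]]
}

# scale grid + frequency-domain filter matrix for series length n
morse_grid <- function(n, dt = 1, gamma = 3, time_bandwidth = 60, voices = 10) {
  if (gamma <= 0) abort("gamma must be positive")
  beta <- time_bandwidth / gamma
  if (beta <= 1) abort("time_bandwidth must exceed gamma (analytic admissibility)")
  wp <- morse_peak_freq(gamma, beta)
  pmin <- 2 * dt
  pmax <- n * dt / 2
  noct <- log2(pmax / pmin)
  periods <- pmin * 2^(seq(0, noct, by = 1 / voices))
  scales <- wp * periods / (2 * pi * dt) # in samples
  omega <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  Psi <- vapply(scales, function(s) morse_hat(s * omega, gamma, beta),
                numeric(n))
  efold1 <- morse_efold(gamma, beta)
  coi_efold <- efold1 * scales * dt # e-folding time per scale, data units
  list(periods = periods, freqs = 1 / periods, scales = scales,
       Psi = Psi, coi_efold = coi_efold, gamma = gamma, beta = beta,
       dt = dt)
}

# CWT power for every column of matrix R (rows = time) at one scale set;
# returns array n x nscale x ncol collapsed by `reduce` (NULL = keep per
# column; "mean" = average power over columns)
cwt_power <- function(R, grid, reduce = c("none", "mean")) {
  reduce <- match.arg(reduce)
  n <- nrow(R)
  X <- mvfft(R)
  ns <- length(grid$periods)
  if (reduce == "mean") {
    out <- matrix(0, n, ns)
    for (j in seq_len(ns)) {
      W <- mvfft(X * grid$Psi[, j], inverse = TRUE) / n
      out[, j] <- rowMeans(Mod(W)^2)
    }
    out
  } else {
    out <- array(0, c(n, ns, ncol(R)))
    for (j in seq_len(ns)) {
      W <- mvfft(X * grid$Psi[, j], inverse = TRUE) / n
      out[, j, ] <- Mod(W)^2
    }
    out
  }
}

# per-time maximum trustworthy period (one-sided e-folding convention)
coi_periods <- function(n, grid) {
  edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * grid$dt
  vapply(edge, function(d) {
    ok <- grid$coi_efold <= d
    if (!any(ok)) 0 else max(grid$periods[ok])
  }, numeric(1))
}

#' Continuous wavelet transform with a generalized Morse wavelet
#'
#' Computes |CWT|^2 of a (typically detrended, standardized) series on a
#' geometric scale grid spanning periods from 2 to n/2 sampling units,
#' with the analytic Morse wavelet (defaults: symmetry parameter 3,
#' time-bandwidth product 60). The cone of influence marks, for each
#' time point, the longest period whose wavelet envelope e-folding time
#' fits inside the distance to the nearest series edge.
#'
#' @param x Numeric series (use [quadratic_detrend()] first for trended
#'   data).
#' @param dt Sampling interval (e.g. 1 year).
#' @param gamma Morse symmetry parameter; default 3.
#' @param time_bandwidth Morse time-bandwidth product; default 60.
#' @param voices Scales per octave; default 10.
#' @return List of class `ecots_cwt`: `power` (time x frequency matrix),
#'   `time`, `freqs`, `periods`, `coi_period` (per-time maximum
#'   trustworthy period) and the Morse parameters.
#' @export
morse_cwt <- function(x, dt = 1, gamma = 3, time_bandwidth = 60, voices = 10) {
  n <- length(x)
  if (n < 8) abort("series too short for wavelet analysis")
  grid <- morse_grid(n, dt, gamma, time_bandwidth, voices)
  P <- cwt_power(matrix(x, n, 1), grid, reduce = "mean")
  structure(list(power = P, time = seq_len(n) * dt, freqs = grid$freqs,
                 periods = grid$periods, coi_period = coi_periods(n, grid),
                 gamma = gamma, time_bandwidth = time_bandwidth,
                 voices = voices, dt = dt),
            class = "ecots_cwt")
}

#' Average wavelet power fields across stations (mean field)
#'
#' Arithmetic mean, cell by cell, of the wavelet power surfaces of
#' several equal-length series: the "mean field" wavelet of a station
#' network. All fields must share the same time and scale grids; the
#' cone of influence is common.
#'
#' @param fields List of `ecots_cwt` objects.
#' @return An `ecots_cwt` whose `power` is the station average, with an
#'   added `n_stations` element.
#' @export
mean_field <- function(fields) {
  stopifnot(length(fields) >= 1, all(vapply(fields, inherits, TRUE, "ecots_cwt")))
  p0 <- fields[[1]]
  for (f in fields[-1]) {
    if (!identical(dim(f$power), dim(p0$power)))
      abort("wavelet fields have different grids")
  }
  p0$power <- Reduce(`+`, lapply(fields, `[[`, "power")) / length(fields)
  p0$n_stations <- length(fields)
  p0
}

# station tibble -> year x station matrix of mean_temp, common years
station_matrix <- function(stations) {
  wide <- tidyr::pivot_wider(
    dplyr::select(stations, dplyr::all_of(c("station_id", "year", "mean_temp"))),
    names_from = "station_id", values_from = "mean_temp")
  wide <- wide[order(wide$year), ]
  yrs <- wide$year
  if (any(diff(yrs) != 1)) abort("station years must be contiguous")
  M <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(M)) abort("all stations must cover the same contiguous years")
  list(years = yrs, M = M)
}

detrend_matrix <- function(M) {
  n <- nrow(M)
  t <- seq_len(n)
  H <- cbind(1, t, t^2)
  Q <- qr.Q(qr(H))
  R <- M - Q %*% crossprod(Q, M) # residuals of quadratic fit, per column
  s <- sqrt(colSums(R^2) / (n - 3))
  if (any(s == 0)) abort("zero residual variance after quadratic detrend")
  sweep(R, 2, s, "/")
}

#' Mean-field Morse wavelet of a station network
#'
#' Quadratically detrends and standardizes each station's annual series,
#' computes each station's Morse wavelet power surface, and averages the
#' surfaces across stations for every time-frequency cell.
#'
#' @param stations Data frame with `station_id`, `year`, `mean_temp`
#'   (coordinates are not needed for the wavelet itself).
#' @inheritParams morse_cwt
#' @return List of class `ecots_meanfield`: `power` (year x frequency),
#'   `years`, `freqs`, `periods`, `coi_period`, `n_stations`.
#' @export
mean_field_wavelet <- function(stations, gamma = 3, time_bandwidth = 60,
                               voices = 10) {
  sm <- station_matrix(stations)
  n <- nrow(sm$M)
  grid <- morse_grid(n, 1, gamma, time_bandwidth, voices)
  P <- cwt_power(detrend_matrix(sm$M), grid, reduce = "mean")
  structure(list(power = P, years = sm$years, freqs = grid$freqs,
                 periods = grid$periods, coi_period = coi_periods(n, grid),
                 n_stations = ncol(sm$M), gamma = gamma,
                 time_bandwidth = time_bandwidth, voices = voices),
            class = "ecots_meanfield")
}

#' Tandem-surrogate significance mask for a mean-field wavelet
#'
#' Builds the null distribution of the mean-field wavelet power under
#' "no timescale dependence" by repeatedly permuting the years of all
#' stations in tandem (the same permutation for every station, so
#' same-year cross-station correlations are preserved exactly),
#' re-detrending, recomputing the mean field, and taking the pointwise
#' upper percentile at every time-frequency cell. Cells of the observed
#' field above the threshold are flagged as hot spots.
#'
#' @param stations Data frame with `station_id`, `year`, `mean_temp`.
#' @param n_surrogates Number of tandem permutations; default 2000.
#' @param seed Integer master seed (bit-reproducible masks).
#' @param prob Upper percentile; default 0.95.
#' @inheritParams morse_cwt
#' @return List of class `ecots_wavelet_sig`: `observed`
#'   (`ecots_meanfield`), `threshold` (matrix), `mask` (logical matrix),
#'   `in_coi` (logical matrix, TRUE where edge effects reach),
#'   `n_surrogates`, `seed`.
#' @export
tandem_surrogate_mask <- function(stations, n_surrogates = 2000, seed = NULL,
                                  prob = 0.95, gamma = 3,
                                  time_bandwidth = 60, voices = 10) {
  sm <- station_matrix(stations)
  n <- nrow(sm$M)
  grid <- morse_grid(n, 1, gamma, time_bandwidth, voices)
  obs_power <- cwt_power(detrend_matrix(sm$M), grid, reduce = "mean")
  ns <- length(grid$periods)
  # streaming pointwise quantile: keep all surrogate fields is n*ns*B
  # doubles; at typical sizes (100 x ~50 x 2000) that is ~80 MB, fine.
  surr <- array(0, c(n, ns, n_surrogates))
  with_seed_(seed, {
    for (b in seq_len(n_surrogates)) {
      Mp <- sm$M[sample.int(n), , drop = FALSE]
      surr[, , b] <- cwt_power(detrend_matrix(Mp), grid, reduce = "mean")
    }
  })
  thr <- apply(surr, c(1, 2), quantile, probs = prob, names = FALSE)
  coi_p <- coi_periods(n, grid)
  in_coi <- outer(seq_len(n), seq_len(ns),
                  function(i, j) grid$periods[j] > coi_p[i])
  observed <- structure(
    list(power = obs_power, years = sm$years, freqs = grid$freqs,
         periods = grid$periods, coi_period = coi_p,
         n_stations = ncol(sm$M), gamma = gamma,
         time_bandwidth = time_bandwidth, voices = voices),
    class = "ecots_meanfield")
  structure(list(observed = observed, threshold = thr,
                 mask = obs_power > thr, in_coi = in_coi,
                 n_surrogates = n_surrogates, seed = seed),
            class = "ecots_wavelet_sig")
}
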