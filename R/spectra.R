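#' Raw periodogram and cross-periodogram internals
#'
#' The periodogram is scaled so that the powers at the positive Fourier
#' frequencies k/n, k = 1..floor(n/2), sum to the sample variance of the
#' (demeaned) series: power_k = 2 |X_k|^2 / (n (n - 1)), with the Nyquist
#' ordinate (even n) not doubled. Only sum-normalized spectra are used
#' downstream, so any variance-proportional scaling is equivalent; this one
#' makes Parseval's identity read "sum(power) == var(x)".
#'
#' @noRd
periodogram_core <- function(x, demean = TRUE) {
  n <- length(x)
  if (n < 8) abort("need at least 8 observations for spectral estimation")
  if (demean) x <- x - mean(x)
  if (var(x) == 0) abort("degenerate series: zero variance")
  X <- fft(x)
  m <- n %/% 2
  p <- 2 * Mod(X[2:(m + 1)])^2 / (n * (n - 1))
  if (n %% 2 == 0) p[m] <- p[m] / 2
  p
}

cross_core <- function(x, y, demean = TRUE) {
  n <- length(x)
  if (length(y) != n) abort("series lengths differ")
  if (n < 8) abort("need at least 8 observations for spectral estimation")
  if (demean) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  X <- fft(x)
  Y <- fft(y)
  m <- n %/% 2
  cs <- 2 * (X[2:(m + 1)] * Conj(Y[2:(m + 1)])) / (n * (n - 1))
  if (n %% 2 == 0) cs[m] <- cs[m] / 2
  list(co = Re(cs), quad = Im(cs))
}

fourier_freqs <- function(n, dt = 1) {
  (1:(n %/% 2)) / (n * dt)
}

#' Iterated Daniell smoothing with clipped endpoint windows
#'
#' Applies one centered moving average per span, in order. Interior points
#' are plain boxcar means; near the ends the window is clipped to the data
#' range and renormalized to unit weight, so a constant sequence is
#' returned unchanged and the output has the same length as the input.
#' Iterating spans (5, 7) convolves to a trapezoidal kernel, the smoother
#' conventionally applied to jagged raw periodogram ordinates.
#'
#' @param x Numeric vector (typically raw spectral powers).
#' @param spans Odd integers >= 3, applied in sequence. Default `c(5, 7)`.
#' @return Numeric vector, same length as `x`.
#' @examples
#' daniell_smooth(c(rep(0, 15), 1, rep(0, 15)))
#' @export
daniell_smooth <- function(x, spans = c(5, 7)) {
  m <- length(x)
  for (s in spans) {
    if (s %% 2 == 0) abort("Daniell spans must be odd")
    if (s < 3) abort("Daniell spans must be >= 3")
    if (m < s) abort("sequence shorter than smoothing span")
  }
  for (s in spans) {
    h <- (s - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(m) - h, 1L)
    hi <- pmin(seq_len(m) + h, m)
    x <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  x
}

# The same smoother as an m x m linear operator, for vectorized surrogate
# computation (smoothed = S %*% raw applies it to every column at once).
daniell_matrix <- function(m, spans = c(5, 7)) {
  S <- diag(m)
  for (s in spans) {
    h <- (s - 1L) %/% 2L
    A <- matrix(0, m, m)
    for (i in seq_len(m)) {
      w <- max(1L, i - h):min(m, i + h)
      A[i, w] <- 1 / length(w)
    }
    S <- A %*% S
  }
  S
}

new_spectrum_tbl <- function(df, meta) {
  out <- as_tibble(df)
  attributes(out) <- c(attributes(out), meta)
  class(out) <- c("ecots_spectrum", class(out))
  out
}

#' Estimate a (smoothed, normalized) power spectrum
#'
#' Computes the FFT periodogram of a uniformly sampled series at the
#' positive Fourier frequencies, optionally smooths it with an iterated
#' clipped Daniell kernel, and optionally normalizes the powers to sum to
#' one so the spectrum reads as the distribution of variance across
#' timescales. No trend is removed; the series mean is subtracted by
#' default and no taper is applied.
#'
#' @param data A data frame with one numeric observation column.
#' @param value Column holding the observations (tidy-eval).
#' @param dt Sampling interval (e.g. 1 for monthly data in months).
#' @param demean Subtract the series mean before the FFT (default TRUE).
#' @param smooth Apply the Daniell smoother (default TRUE).
#' @param spans Daniell spans, odd integers; default `c(5, 7)`.
#' @param normalize Divide powers by their sum (default TRUE).
#' @return A tibble of class `ecots_spectrum` with columns `frequency`
#'   (cycles per sampling unit), `period` (= 1/frequency) and `power`,
#'   carrying attributes `n`, `dt`, `smoothed`, `spans`, `normalized`
#'   and `variance` (sample variance of the demeaned series).
#' @examples
#' d <- tibble::tibble(x = as.numeric(LakeHuron))
#' est_spectrum(d, x)
#' @export
est_spectrum <- function(data, value, dt = 1, demean = TRUE, smooth = TRUE,
                         spans = c(5, 7), normalize = TRUE) {
  x <- pull_num(data, {{ value }})
  p <- periodogram_core(x, demean = demean)
  if (smooth) p <- daniell_smooth(p, spans)
  if (normalize) {
    s <- sum(p)
    if (s <= 0) abort("all-zero spectrum cannot be normalized")
    p <- p / s
  }
  f <- fourier_freqs(length(x), dt)
  new_spectrum_tbl(
    tibble(frequency = f, period = 1 / f, power = p),
    list(n = length(x), dt = dt, smoothed = smooth,
         spans = if (smooth) spans else NULL, normalized = normalize,
         variance = var(x - if (demean) mean(x) else 0))
  )
}

#' Estimate a (smoothed, normalized) cospectrum and quadrature spectrum
#'
#' The cross-spectrum of a bivariate series decomposes the covariance by
#' frequency: its real part (cospectrum) is the in-phase covariance
#' density and its imaginary part (quadrature spectrum) the 90-degree
#' phase-shifted part. When `normalize = TRUE` the cospectrum is rescaled
#' so that it sums exactly to the Pearson correlation of the two raw
#' series, making per-band sums read as correlation components.
#'
#' @param data A data frame with two numeric observation columns.
#' @param value1,value2 Columns holding the two series (tidy-eval).
#' @inheritParams est_spectrum
#' @return A tibble of class `ecots_cospectrum` with columns `frequency`,
#'   `period`, `cospectrum`, `quadrature`; attribute `r_total` holds the
#'   Pearson correlation of the input series.
#' @examples
#' d <- tibble::tibble(x = rnorm(64), y = rnorm(64))
#' cs <- est_cospectrum(d, x, y)
#' sum(cs$cospectrum) - cor(d$x, d$y)  # ~ 0
#' @export
est_cospectrum <- function(data, value1, value2, dt = 1, demean = TRUE,
                           smooth = TRUE, spans = c(5, 7), normalize = TRUE) {
  x <- pull_num(data, {{ value1 }}, "value1")
  y <- pull_num(data, {{ value2 }}, "value2")
  if (var(x) == 0 || var(y) == 0) abort("degenerate series: zero variance")
  cc <- cross_core(x, y, demean = demean)
  co <- cc$co
  qu <- cc$quad
  if (smooth) {
    co <- daniell_smooth(co, spans)
    qu <- daniell_smooth(qu, spans)
  }
  r <- cor(x, y)
  if (normalize) {
    # raw cospectrum sums to the sample covariance (Parseval); dividing by
    # sd(x) sd(y) turns the sum into r. Endpoint clipping in the smoother
    # perturbs the sum slightly, so pin it to r exactly afterwards.
    sc <- sd(x) * sd(y)
    co <- co / sc
    qu <- qu / sc
    s <- sum(co)
    if (abs(s) > 1e-12 && abs(r) > 1e-12) co <- co * (r / s)
  }
  f <- fourier_freqs(length(x), dt)
  out <- as_tibble(tibble(frequency = f, period = 1 / f,
                          cospectrum = co, quadrature = qu))
  attributes(out) <- c(attributes(out),
                       list(n = length(x), dt = dt, smoothed = smooth,
                            spans = if (smooth) spans else NULL,
                            normalized = normalize, r_total = r))
  class(out) <- c("ecots_cospectrum", class(out))
  out
}

#' Partition total correlation by timescale band
#'
#' Sums a normalized, unsmoothed cospectrum over timescale bands so the
#' band sums decompose the Pearson correlation: R = R_1 + ... + R_B. A
#' frequency f belongs to the band with edges (a, b], a < 1/f <= b, with
#' ties at an edge assigned to the shorter-timescale band.
#'
#' @param cospec An `ecots_cospectrum` (normalized; use `smooth = FALSE`
#'   for an exact decomposition).
#' @param edges Timescale cut points in the `period` units, descending or
#'   ascending; default `c(12, 4)` gives bands >12, 4-12 and <=4.
#' @return A tibble with columns `band` (label), `min_period`,
#'   `max_period`, `correlation` and `n_freq`; attribute `total` holds the
#'   full correlation (the sum of the `correlation` column).
#' @export
partition_correlation <- function(cospec, edges = c(12, 4)) {
  stopifnot(is.data.frame(cospec), all(c("period", "cospectrum") %in% names(cospec)))
  if (!isTRUE(attr(cospec, "normalized")))
    warn("partitioning a non-normalized cospectrum; band sums are covariances, not correlations")
  edges <- sort(unique(as.numeric(edges)), decreasing = TRUE)
  if (any(edges <= min(cospec$period)) && any(edges > max(cospec$period)))
    NULL # edges may legitimately sit anywhere inside or outside the grid
  bounds <- c(Inf, edges, 0)
  labs <- character(length(bounds) - 1)
  res <- vector("list", length(labs))
  for (b in seq_along(labs)) {
    hi <- bounds[b]
    lo <- bounds[b + 1]
    sel <- cospec$period > lo & cospec$period <= hi
    labs[b] <- if (is.infinite(hi)) paste0(">", lo)
    else if (lo == 0) paste0("<=", hi)
    else paste0(lo, "-", hi)
    res[[b]] <- tibble(band = labs[b], min_period = lo, max_period = hi,
                       correlation = sum(cospec$cospectrum[sel]),
                       n_freq = sum(sel))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "total") <- sum(cospec$cospectrum)
  out
}

#' Spectral exponent: log-log slope of a power spectrum
#'
#' The spectral exponent is the ordinary least-squares slope of
#' log(power) against log(frequency) over the full frequency grid
#' (natural logs; the slope is base-invariant). Negative exponents mark
#' red (long-timescale-dominated) spectra, positive exponents blue
#' spectra, zero white noise.
#'
#' @param spectrum An `ecots_spectrum` or any data frame with `frequency`
#'   and `power` columns.
#' @return One-row tibble with `exponent`, `intercept` and `n_freq`.
#' @examples
#' s <- tibble::tibble(frequency = (1:32) / 64, power = 2 * (1:32) / 64)
#' spectral_exponent(s)$exponent  # exactly 1
#' @export
spectral_exponent <- function(spectrum) {
  stopifnot(is.data.frame(spectrum), all(c("frequency", "power") %in% names(spectrum)))
  p <- spectrum$power
  f <- spectrum$frequency
  if (any(p < 0)) abort("negative spectral power; exponent undefined")
  zero <- p == 0
  if (any(zero)) {
    if (mean(zero) > 0.2) abort("zero spectral power; exponent undefined")
    warn(sprintf("excluding %d zero-power frequencies from exponent regression", sum(zero)))
    p <- p[!zero]
    f <- f[!zero]
  }
  lf <- log(f)
  lp <- log(p)
  sl <- sum((lf - mean(lf)) * (lp - mean(lp))) / sum((lf - mean(lf))^2)
  tibble(exponent = sl, intercept = mean(lp) - sl * mean(lf), n_freq = length(f))
}

# exponent from a bare power vector on the unit-dt Fourier grid; hot path
# for sweeps (no tibble overhead)
exponent_core <- function(p, f) {
  lf <- log(f)
  lp <- log(p)
  sum((lf - mean(lf)) * (lp - mean(lp))) / sum((lf - mean(lf))^2)
}
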