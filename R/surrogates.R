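#' Tandem permutation of a multivariate time series
#'
#' Reorders the rows of `data` by one shared random permutation, so the
#' pairing of simultaneous observations is preserved. Every
#' time-independent statistic (means, variances, marginal distributions,
#' and all cross-correlations between columns) is exactly unchanged;
#' only the time ordering, and hence all autocorrelation, is destroyed.
#' This is the null model for "no timescale dependence".
#'
#' @param data Data frame whose rows are time-ordered observations.
#' @param seed Integer seed for reproducibility (NULL = use current RNG).
#' @return `data` with rows permuted, as a tibble.
#' @export
tandem_shuffle <- function(data, seed = NULL) {
  n <- nrow(data)
  idx <- with_seed_(seed, sample.int(n))
  as_tibble(data[idx, , drop = FALSE])
}

#' Permutation-surrogate significance bands for spectra and cospectra
#'
#' Builds pointwise null bands by repeatedly tandem-shuffling the input
#' series, recomputing the smoothed normalized spectrum (and, for
#' bivariate input, cospectrum) of each surrogate exactly as for the
#' observed data, and taking per-frequency empirical percentiles: the
#' 95th percentile for spectra (one-sided, since power is positive) and
#' the 2.5th/97.5th percentiles for the cospectrum (two-sided). Bands
#' are pointwise, not simultaneous, and bit-reproducible given `seed`.
#'
#' @param data Data frame with one or two numeric series columns.
#' @param value1 First series column (tidy-eval).
#' @param value2 Optional second series column.
#' @param spans Daniell spans used for every surrogate (and that should
#'   be used for the observed estimate being compared).
#' @param n_surrogates Number of random reshuffles; default 2000.
#' @param seed Integer master seed; surrogate i uses the i-th draw of a
#'   single sequential stream.
#' @param spectrum_prob Upper percentile for the spectra (default 0.95).
#' @param cospectrum_probs Two-sided percentiles for the cospectrum.
#' @return Tibble with `frequency`, `period`, `spec1_upper` and, when
#'   `value2` is given, `spec2_upper`, `co_lower`, `co_upper`;
#'   attributes `n_surrogates` and `seed`.
#' @export
surrogate_bands <- function(data, value1, value2 = NULL, spans = c(5, 7),
                            n_surrogates = 2000, seed = NULL,
                            spectrum_prob = 0.95,
                            cospectrum_probs = c(0.025, 0.975)) {
  x <- pull_num(data, {{ value1 }}, "value1")
  has_y <- !rlang::quo_is_null(enquo(value2))
  y <- if (has_y) pull_num(data, {{ value2 }}, "value2") else NULL
  if (n_surrogates < 100)
    warn("fewer than 100 surrogates: percentile resolution is poor")
  n <- length(x)
  m <- n %/% 2
  scale <- 2 / (n * (n - 1))
  Sm <- daniell_matrix(m, spans)
  idx <- with_seed_(seed, {
    vapply(seq_len(n_surrogates), function(i) sample.int(n), integer(n))
  })

  xc <- x - mean(x)
  X <- mvfft(matrix(xc[idx], n, n_surrogates))[2:(m + 1), , drop = FALSE]
  P1 <- Mod(X)^2 * scale
  if (n %% 2 == 0) P1[m, ] <- P1[m, ] / 2
  P1 <- Sm %*% P1
  P1 <- sweep(P1, 2, colSums(P1), "/")
  qs <- function(M, p) apply(M, 1, quantile, probs = p, names = FALSE)
  f <- fourier_freqs(n)
  out <- tibble(frequency = f, period = 1 / f,
                spec1_upper = qs(P1, spectrum_prob))

  if (has_y) {
    yc <- y - mean(y)
    Y <- mvfft(matrix(yc[idx], n, n_surrogates))[2:(m + 1), , drop = FALSE]
    P2 <- Mod(Y)^2 * scale
    if (n %% 2 == 0) P2[m, ] <- P2[m, ] / 2
    P2 <- Sm %*% P2
    P2 <- sweep(P2, 2, colSums(P2), "/")
    CO <- Re(X * Conj(Y)) * scale
    if (n %% 2 == 0) CO[m, ] <- CO[m, ] / 2
    CO <- (Sm %*% CO) / (sd(x) * sd(y))
    r <- cor(x, y)
    if (abs(r) > 1e-12) {
      s <- colSums(CO)
      ok <- abs(s) > 1e-12
      CO[, ok] <- sweep(CO[, ok, drop = FALSE], 2, r / s[ok], "*")
    }
    out$spec2_upper <- qs(P2, spectrum_prob)
    out$co_lower <- qs(CO, min(cospectrum_probs))
    out$co_upper <- qs(CO, max(cospectrum_probs))
  }
  attr(out, "n_surrogates") <- n_surrogates
  attr(out, "seed") <- seed
  class(out) <- c("ecots_bands", class(out))
  out
}

#' Longest-period crossing of a surrogate band
#'
#' Returns the longest period (timescale) at the boundary of the longest
#' contiguous run of frequencies where the observed curve exceeds the
#' band, or NA when there is no exceedance. This is a descriptive
#' summary of where an observed spectrum "crosses" its null band.
#'
#' @param observed Numeric vector of observed per-frequency values.
#' @param band Numeric vector, the band to exceed, same length.
#' @param period Numeric vector of periods for the grid.
#' @return Single numeric period or NA.
#' @export
band_crossing <- function(observed, band, period) {
  ex <- observed > band
  if (!any(ex)) return(NA_real_)
  r <- rle(ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  max(period[starts[best]:ends[best]])
}
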