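#' Specify a bivariate noise spectral matrix
#'
#' A noise spectrum specification fixes, at every frequency f in
#' (0, 0.5], a 2x2 spectral matrix: identical spectra S(f) on the
#' diagonal and a cospectrum equal to a constant fraction c of S(f) off
#' the diagonal, with zero quadrature (no frequency-specific phase
#' shifts). The implied per-frequency correlation is c at all
#' frequencies, so generated series pairs have Pearson correlation ~ c
#' regardless of color.
#'
#' @param power_fun Function of frequency returning the (nonnegative)
#'   spectral power S(f) on f in \[0, 0.5\].
#' @param cospectrum_fraction Constant c in \[-1, 1\]; default 0.9.
#' @param label Optional description.
#' @return Object of class `noise_spectrum`.
#' @seealso [linear_noise_spec()] for the blue-white-red linear family.
#' @export
noise_spectrum <- function(power_fun, cospectrum_fraction = 0.9, label = NULL) {
  stopifnot(is.function(power_fun))
  if (abs(cospectrum_fraction) > 1)
    abort("cospectrum_fraction must lie in [-1, 1]")
  structure(list(power_fun = power_fun, c = cospectrum_fraction,
                 label = label),
            class = "noise_spectrum")
}

#' The linear blue-white-red noise spectrum family
#'
#' S(f) = mean_power + slope (f - 0.25) on f in \[0, 0.5\]: slope +2 is
#' the bluest member (S rises from 0 at f = 0 to 1 at f = 0.5), slope 0
#' is white noise with constant power 0.5, slope -2 the reddest member.
#' The average power over the frequency range, and hence the variance of
#' generated series, is `mean_power` for every slope, so a slope sweep
#' changes only the timescale composition of the noise, not its total
#' variance.
#'
#' @param slope Spectral slope, |slope| <= 4 * mean_power so S >= 0.
#' @param mean_power Average power (= series variance); default 0.5.
#' @param cospectrum_fraction Constant cospectrum fraction; default 0.9.
#' @return Object of class `noise_spectrum` with extra fields `slope`
#'   and `mean_power`.
#' @examples
#' linear_noise_spec(-2)   # reddest
#' linear_noise_spec(0)    # white
#' @export
linear_noise_spec <- function(slope, mean_power = 0.5, cospectrum_fraction = 0.9) {
  if (abs(slope) > 4 * mean_power + 1e-12)
    abort("slope too steep: S(f) would be negative somewhere on [0, 0.5]")
  spec <- noise_spectrum(function(f) mean_power + slope * (f - 0.25),
                         cospectrum_fraction,
                         label = sprintf("linear slope %.3g", slope))
  spec$slope <- slope
  spec$mean_power <- mean_power
  spec
}

#' @export
print.noise_spectrum <- function(x, ...) {
  cat("Noise spectrum", if (!is.null(x$label)) paste0("(", x$label, ")"),
      sprintf("| cospectrum fraction %.3g\n", x$c))
  invisible(x)
}

# Synthesize `nrep` independent bivariate realizations of length n from a
# noise_spectrum, as two n x nrep matrices. Spectral-matrix ("Chambers")
# synthesis: at each positive Fourier frequency, factor the 2x2 spectral
# matrix by Cholesky, scale independent standard complex Gaussian draws,
# enforce Hermitian symmetry, inverse-FFT. The DC coefficient is zero
# (mean-zero noise); the Nyquist coefficient (even n) is drawn real with
# doubled variance so each series' expected variance equals the grid mean
# of S (= mean_power for the linear family).
noise_matrix <- function(spec, n, nrep = 1) {
  m <- n %/% 2
  fk <- (1:m) / n
  S <- pmax(spec$power_fun(fk), 0)
  cc <- spec$c
  # upper-triangular Cholesky factor of [[1, c], [c, 1]]
  l11 <- 1
  l12 <- cc
  l22 <- sqrt(max(0, 1 - cc^2))
  v <- n^2 / (2 * m) # E|X_k|^2 = v * S(f_k) makes var(series) = mean(S)
  npos <- if (n %% 2 == 0) m - 1L else m
  X1 <- matrix(0 + 0i, n, nrep)
  X2 <- matrix(0 + 0i, n, nrep)
  z1 <- matrix(complex(real = rnorm(npos * nrep), imaginary = rnorm(npos * nrep)) / sqrt(2),
               npos, nrep)
  z2 <- matrix(complex(real = rnorm(npos * nrep), imaginary = rnorm(npos * nrep)) / sqrt(2),
               npos, nrep)
  amp <- sqrt(v * S[seq_len(npos)])
  X1[2:(npos + 1), ] <- amp * (l11 * z1)
  X2[2:(npos + 1), ] <- amp * (l12 * z1 + l22 * z2)
  X1[n:(n - npos + 1), ] <- Conj(X1[2:(npos + 1), , drop = FALSE])
  X2[n:(n - npos + 1), ] <- Conj(X2[2:(npos + 1), , drop = FALSE])
  if (n %% 2 == 0) {
    w1 <- rnorm(nrep)
    w2 <- rnorm(nrep)
    a <- sqrt(2 * v * S[m])
    X1[m + 1, ] <- a * (l11 * w1)
    X2[m + 1, ] <- a * (l12 * w1 + l22 * w2)
  }
  e1 <- mvfft(X1, inverse = TRUE) / n
  e2 <- mvfft(X2, inverse = TRUE) / n
  if (max(abs(Im(e1)), abs(Im(e2))) > 1e-8)
    abort("internal error: synthesized noise is not real-valued")
  list(eps1 = Re(e1), eps2 = Re(e2))
}

#' Generate correlated colored noise from a spectral matrix
#'
#' Draws one bivariate realization whose expected periodogram and
#' cross-periodogram match the target spectral matrix (Chambers-style
#' frequency-domain synthesis; see [noise_spectrum()]). Each series has
#' mean zero and variance converging to the grid average of S(f) as n
#' grows; with the default linear family that is 0.5.
#'
#' @param spec A `noise_spectrum`, e.g. from [linear_noise_spec()].
#' @param n Series length.
#' @param seed Integer seed (NULL = use current RNG state).
#' @return Tibble with columns `t`, `eps1`, `eps2` and attribute `spec`.
#' @examples
#' eps <- generate_noise(linear_noise_spec(-2), 256, seed = 1)
#' var(eps$eps1); cor(eps$eps1, eps$eps2)
#' @export
generate_noise <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "noise_spectrum"))
  if (n < 8) abort("n must be at least 8")
  e <- with_seed_(seed, noise_matrix(spec, n, 1))
  out <- tibble(t = seq_len(n), eps1 = e$eps1[, 1], eps2 = e$eps2[, 1])
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Spectral exponents realized by a noise (or any bivariate) series pair
#'
#' Estimates each series' unsmoothed normalized spectrum and returns its
#' spectral exponent, the log-log regression slope used to read the
#' realized color of a generated noise pair.
#'
#' @param noise Tibble with `eps1` and `eps2` columns (as produced by
#'   [generate_noise()]).
#' @return Tibble with columns `series` and `exponent`.
#' @export
realized_exponent <- function(noise) {
  stopifnot(all(c("eps1", "eps2") %in% names(noise)))
  e1 <- spectral_exponent(est_spectrum(noise, eps1, smooth = FALSE))
  e2 <- spectral_exponent(est_spectrum(noise, eps2, smooth = FALSE))
  tibble(series = c("eps1", "eps2"),
         exponent = c(e1$exponent, e2$exponent))
}
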