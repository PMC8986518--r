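test_that("raw periodogram satisfies the Parseval scaling for arbitrary input", {
  withr::with_seed(11, {
    for (n in c(64, 101, 140)) {
      x <- rnorm(n) + sin(2 * pi * seq_len(n) / 9)
      p <- ecotimescale:::periodogram_core(x)
      expect_equal(sum(p), var(x), tolerance = 1e-12)
    }
  })
})

test_that("a pure cosine concentrates all power at its frequency", {
  t <- 1:64
  d <- tibble::tibble(x = cos(2 * pi * t / 4))
  s <- est_spectrum(d, x, smooth = FALSE, normalize = FALSE)
  at <- which.min(abs(s$frequency - 0.25))
  expect_gt(s$power[at] / sum(s$power), 1 - 1e-10)
  expect_lt(max(s$power[-at]), 1e-10)
})

test_that("constant series is rejected as degenerate", {
  d <- tibble::tibble(x = rep(3, 50))
  expect_error(est_spectrum(d, x), "degenerate")
})

test_that("AR(1) periodogram decile ratio matches the closed-form spectrum", {
  withr::with_seed(21, {
    phi <- 0.8
    x <- as.numeric(arima.sim(list(ar = phi), 4096))
    p <- ecotimescale:::periodogram_core(x)
    f <- ecotimescale:::fourier_freqs(4096)
    dec <- floor(length(f) / 10)
    lo <- 1:dec
    hi <- (length(f) - dec + 1):length(f)
    obs_ratio <- mean(p[lo]) / mean(p[hi])
    th_ratio <- mean(ar1_spectrum(f[lo], phi)) / mean(ar1_spectrum(f[hi], phi))
    expect_gt(obs_ratio, 10) # low frequencies dominate strongly
    expect_lt(abs(obs_ratio / th_ratio - 1), 0.10)
  })
})

test_that("cross-periodogram identities hold: self, negation, quadrature phase", {
  withr::with_seed(31, {
    d <- tibble::tibble(x = rnorm(128))
    d$negx <- -d$x
    cs <- est_cospectrum(d, x, x, smooth = FALSE, normalize = FALSE)
    ps <- est_spectrum(d, x, smooth = FALSE, normalize = FALSE)
    expect_equal(cs$cospectrum, ps$power, tolerance = 1e-12)
    expect_lt(max(abs(cs$quadrature)), 1e-12)
    csn <- est_cospectrum(d, x, negx, smooth = FALSE, normalize = FALSE)
    expect_equal(csn$cospectrum, -ps$power, tolerance = 1e-12)
  })
  # quarter-period-shifted cosines: covariance lives in the quadrature
  t <- 1:64
  d2 <- tibble::tibble(a = cos(2 * pi * t / 8), b = cos(2 * pi * (t - 2) / 8))
  cq <- est_cospectrum(d2, a, b, smooth = FALSE, normalize = FALSE)
  at <- which.min(abs(cq$frequency - 1 / 8))
  expect_lt(abs(cq$cospectrum[at]), 1e-10)
  expect_gt(abs(cq$quadrature[at]), 0.4)
})

test_that("daniell smoothing matches the brute-force clipped-window oracle", {
  withr::with_seed(41, {
    for (m in c(31, 70)) {
      x <- rexp(m)
      expect_equal(daniell_smooth(x, c(5, 7)), smooth_oracle(x, c(5, 7)),
                   tolerance = 1e-12)
      expect_equal(daniell_smooth(x, 5), smooth_oracle(x, 5), tolerance = 1e-12)
    }
  })
  # impulse response away from the edges is the boxcar*boxcar trapezoid
  x <- numeric(31); x[16] <- 1
  y <- daniell_smooth(x, c(5, 7))
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_equal(y[16], 1 / 7, tolerance = 1e-12) # flat top of the trapezoid
  expect_equal(y, rev(y), tolerance = 1e-12)    # symmetric kernel
})

test_that("daniell smoothing preserves constants and interior lines, rejects even spans", {
  expect_equal(daniell_smooth(rep(2.5, 20), c(5, 7)), rep(2.5, 20))
  ramp <- seq(0, 1, length.out = 40)
  sm <- daniell_smooth(ramp, c(5, 7))
  expect_equal(sm[6:35], ramp[6:35], tolerance = 1e-12)
  expect_error(daniell_smooth(1:20, c(4, 7)), "odd")
  expect_error(daniell_smooth(1:4, 7), "shorter")
})

test_that("normalized spectra sum to one and preserve shape", {
  withr::with_seed(51, {
    d <- tibble::tibble(x = rnorm(140))
    s <- est_spectrum(d, x)
    expect_equal(sum(s$power), 1, tolerance = 1e-9)
    raw <- est_spectrum(d, x, normalize = FALSE)
    expect_equal(s$power / s$power[1], raw$power / raw$power[1], tolerance = 1e-9)
  })
})

test_that("normalized cospectrum sums to the Pearson correlation (property)", {
  withr::with_seed(61, {
    for (i in 1:8) {
      n <- sample(c(60, 101, 140), 1)
      x <- rnorm(n)
      y <- 0.5 * x + rnorm(n) * runif(1, 0.2, 2)
      d <- tibble::tibble(x = x, y = y)
      for (sm in c(TRUE, FALSE)) {
        cs <- est_cospectrum(d, x, y, smooth = sm)
        expect_equal(sum(cs$cospectrum), cor(x, y), tolerance = 1e-6)
      }
    }
  })
})

test_that("independent white noise has near-zero cospectral sum", {
  withr::with_seed(71, {
    d <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4))
    cs <- est_cospectrum(d, x, y)
    expect_lt(abs(sum(cs$cospectrum)), 0.05) # ~2/sqrt(n) sampling bound
  })
})

test_that("band partition sums exactly to the total correlation", {
  withr::with_seed(81, {
    d <- tibble::tibble(x = rnorm(140), y = rnorm(140))
    cs <- est_cospectrum(d, x, y, smooth = FALSE)
    part <- partition_correlation(cs, c(12, 4))
    expect_equal(sum(part$correlation), sum(cs$cospectrum), tolerance = 1e-12)
    expect_equal(attr(part, "total"), cor(d$x, d$y), tolerance = 1e-6)
    expect_equal(sum(part$n_freq), nrow(cs))
    # one band covering everything equals the total
    whole <- partition_correlation(cs, numeric(0))
    expect_equal(whole$correlation, sum(cs$cospectrum), tolerance = 1e-12)
    # two complementary bands add exactly
    two <- partition_correlation(cs, 12)
    expect_equal(sum(two$correlation), sum(cs$cospectrum), tolerance = 1e-12)
  })
})

test_that("correlation confined to long timescales lands in the long band", {
  d <- bandlimited_pair(240, cut = 12, seed = 5)
  cs <- est_cospectrum(d, x, y, smooth = FALSE)
  part <- partition_correlation(cs, c(12, 4))
  expect_gt(part$correlation[1] / sum(part$correlation), 0.9)
})

test_that("spectral exponent is exact for power-law spectra", {
  f <- (1:32) / 64
  expect_equal(spectral_exponent(tibble::tibble(frequency = f, power = 2 * f))$exponent, 1)
  expect_equal(spectral_exponent(tibble::tibble(frequency = f, power = rep(3, 32)))$exponent, 0)
  expect_equal(spectral_exponent(tibble::tibble(frequency = f, power = 1 / f))$exponent, -1)
  for (p in c(-1.7, 0.4, 2.3)) {
    s <- tibble::tibble(frequency = f, power = 0.7 * f^p)
    expect_equal(spectral_exponent(s)$exponent, p, tolerance = 1e-12)
  }
})

test_that("zero spectral powers are rejected or excluded with a warning", {
  f <- (1:30) / 60
  allbad <- tibble::tibble(frequency = f, power = c(rep(0, 10), f[11:30]))
  expect_error(spectral_exponent(allbad), "zero spectral power")
  onebad <- tibble::tibble(frequency = f, power = c(f[1:29], 0))
  expect_warning(res <- spectral_exponent(onebad), "excluding")
  expect_equal(res$n_freq, 29)
  expect_equal(res$exponent, 1, tolerance = 1e-12)
})
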