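test_that("linear spectrum family has the stated endpoints and constant mean power", {
  blue <- linear_noise_spec(2)
  white <- linear_noise_spec(0)
  red <- linear_noise_spec(-2)
  expect_equal(blue$power_fun(0), 0)
  expect_equal(blue$power_fun(0.5), 1)
  expect_equal(red$power_fun(0), 1)
  expect_equal(red$power_fun(0.5), 0)
  expect_equal(white$power_fun(c(0, 0.25, 0.5)), rep(0.5, 3))
  f <- seq(0, 0.5, length.out = 1001)
  for (b in c(-2, -0.8, 1.3)) {
    expect_equal(mean(linear_noise_spec(b)$power_fun(f)), 0.5, tolerance = 1e-9)
  }
  expect_error(linear_noise_spec(2.5), "negative")
  expect_error(noise_spectrum(function(f) f, cospectrum_fraction = 1.2), "\\[-1, 1\\]")
})

test_that("generated noise matches the target variance and cross-correlation", {
  for (b in c(-2, 0, 2)) {
    eps <- generate_noise(linear_noise_spec(b), 2^14, seed = 100 + b)
    expect_equal(var(eps$eps1), 0.5, tolerance = 0.03)
    expect_equal(var(eps$eps2), 0.5, tolerance = 0.03)
    expect_equal(cor(eps$eps1, eps$eps2), 0.9, tolerance = 0.022)
    expect_lt(abs(mean(eps$eps1)), 0.05)
  }
  # white noise: no lag-1 autocorrelation
  w <- generate_noise(linear_noise_spec(0), 2^14, seed = 7)
  r1 <- cor(w$eps1[-1], w$eps1[-2^14])
  expect_lt(abs(r1), 0.03)
})

test_that("noise generation is seed-deterministic and real-valued", {
  a <- generate_noise(linear_noise_spec(-1), 256, seed = 42)
  b <- generate_noise(linear_noise_spec(-1), 256, seed = 42)
  expect_identical(a, b)
  expect_true(all(is.finite(a$eps1)))
})

test_that("realized spectral exponent of blue noise is the exact log-log slope", {
  eps <- generate_noise(linear_noise_spec(2), 2^14, seed = 13)
  re <- realized_exponent(eps)
  # S = 2f is exactly log-log linear with slope 1
  expect_equal(re$exponent, c(1, 1), tolerance = 0.1)
  sm <- est_spectrum(eps, eps1, smooth = TRUE, spans = c(5, 7))
  expect_equal(spectral_exponent(sm)$exponent, 1, tolerance = 0.1)
})

test_that("short white-noise realizations have unbiased exponents on average", {
  withr::with_seed(14, {
    e <- ecotimescale:::noise_matrix(linear_noise_spec(0), 100, 2000)
    me <- mean(ecotimescale:::matrix_exponents(e$eps1))
    expect_lt(abs(me), 0.05)
  })
})

test_that("averaged periodograms recover the full target spectral matrix", {
  withr::with_seed(15, {
    n <- 128
    nrep <- 800
    spec <- linear_noise_spec(-1.2, 0.5, 0.9)
    e <- ecotimescale:::noise_matrix(spec, n, nrep)
    m <- n %/% 2
    f <- (1:m) / n
    pos <- function(M) mvfft(M)[2:(m + 1), ]
    X <- pos(e$eps1)
    Y <- pos(e$eps2)
    sc <- 2 / (n * (n - 1))
    fix_nyq <- function(P) { P[m, ] <- P[m, ] / 2; P }
    P1 <- rowMeans(fix_nyq(Mod(X)^2 * sc))
    P2 <- rowMeans(fix_nyq(Mod(Y)^2 * sc))
    CO <- rowMeans(fix_nyq(Re(X * Conj(Y)) * sc))
    QU <- rowMeans(fix_nyq(Im(X * Conj(Y)) * sc))
    # periodogram sums to the variance over m frequencies: target density
    # per frequency is S(f)/m scaled to total 0.5
    tgt <- spec$power_fun(f)
    tgt <- tgt / sum(tgt) * 0.5 * (n / (n - 1))
    iae <- function(est, target) sum(abs(est - target)) / sum(abs(target))
    expect_lt(iae(P1, tgt), 0.05)
    expect_lt(iae(P2, tgt), 0.05)
    expect_lt(iae(CO, 0.9 * tgt), 0.05)
    expect_lt(max(abs(QU)), 0.01 * max(tgt) * m) # quadrature target is zero
  })
})

test_that("sample variance is independent of spectral slope", {
  withr::with_seed(16, {
    vars <- vapply(seq(-2, 2, by = 1), function(b) {
      e <- ecotimescale:::noise_matrix(linear_noise_spec(b), 256, 100)
      mean(apply(e$eps1, 2, var))
    }, numeric(1))
    expect_true(all(abs(vars - 0.5) < 0.05))
  })
})
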