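# Independent brute-force oracles used across the suite.

# Clipped-window moving-average smoother as an explicit double loop:
# the reference for daniell_smooth.
smooth_oracle <- function(x, spans) {
  m <- length(x)
  for (s in spans) {
    h <- (s - 1) / 2
    out <- numeric(m)
    for (i in seq_len(m)) {
      w <- max(1, i - h):min(m, i + h)
      out[i] <- sum(x[w]) / length(w)
    }
    x <- out
  }
  x
}

# Theoretical AR(1) spectral density (unit innovation variance), in the
# same "sum over positive Fourier frequencies ~ variance" scaling family.
ar1_spectrum <- function(f, phi) 1 / (1 - 2 * phi * cos(2 * pi * f) + phi^2)

# Naive scalar iteration of the stochastic competition map, step by step.
lv_oracle <- function(p, N0, eps1, eps2) {
  Tn <- length(eps1)
  N1 <- numeric(Tn + 1); N2 <- numeric(Tn + 1)
  N1[1] <- N0[1]; N2[1] <- N0[2]
  for (t in seq_len(Tn)) {
    g1 <- p$r1 * (p$K1 - N1[t] - p$alpha * N2[t]) / p$K1 + p$sigma1 * eps1[t]
    g2 <- p$r2 * (p$K2 - N2[t] - p$beta * N1[t]) / p$K2 + p$sigma2 * eps2[t]
    N1[t + 1] <- N1[t] * exp(min(max(g1, -p$clamp), p$clamp))
    N2[t + 1] <- N2[t] * exp(min(max(g2, -p$clamp), p$clamp))
    if (p$extinction_fraction > 0) {
      if (N1[t + 1] < p$extinction_fraction * p$K1) N1[t + 1] <- 0
      if (N2[t + 1] < p$extinction_fraction * p$K2) N2[t + 1] <- 0
    }
  }
  list(N1 = N1, N2 = N2)
}

# Bivariate series sharing only a band-limited (period > cut) component.
bandlimited_pair <- function(n, cut = 12, seed = 1) {
  withr::with_seed(seed, {
    ks <- which((1:(n %/% 2)) / n < 1 / cut)
    t <- seq_len(n)
    s <- rowSums(vapply(ks, function(k)
      cos(2 * pi * k * t / n + runif(1, 0, 2 * pi)), numeric(n)))
    tibble::tibble(x = s + rnorm(n, 0, 0.05), y = s + rnorm(n, 0, 0.05))
  })
}
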