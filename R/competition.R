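#' Parameters of the stochastic discrete-time Lotka-Volterra model
#'
#' The model advances two competing populations as
#' N_i(t+1) = N_i(t) exp\[ r_i (K_i - N_i - comp_i) / K_i + sigma_i eps_i(t) \],
#' where comp_1 = alpha N_2 and comp_2 = beta N_1, with an absorbing
#' extinction floor: after each step any population below
#' `extinction_fraction * K_i` is set to zero and stays there. Species 1
#' plays the role of a native species, species 2 of an invader whose
#' competitive effect alpha is varied. Defaults are the undercompensatory
#' regime used throughout the package: r = 0.3, K = 50, sigma = 0.75,
#' beta = 0.25, a 5% extinction floor, and 100 time steps.
#'
#' @param r1,r2 Intrinsic rates of increase (> 0).
#' @param K1,K2 Carrying capacities (> 0).
#' @param alpha Effect of species 2 on species 1 (>= 0).
#' @param beta Effect of species 1 on species 2 (>= 0).
#' @param sigma1,sigma2 Environmental noise scales (> 0).
#' @param extinction_fraction Absorbing floor as a fraction of K in
#'   \[0, 1); use 0 to disable extinction (as for spectral summaries).
#' @param steps Number of time steps T.
#' @param clamp Bound on the exponent argument, guarding overflow.
#' @return Object of class `competition_params`.
#' @export
competition_params <- function(r1 = 0.3, r2 = 0.3, K1 = 50, K2 = 50,
                               alpha = 0.25, beta = 0.25,
                               sigma1 = 0.75, sigma2 = 0.75,
                               extinction_fraction = 0.05,
                               steps = 100, clamp = 50) {
  stopifnot(r1 > 0, r2 > 0, K1 > 0, K2 > 0, alpha >= 0, beta >= 0,
            sigma1 > 0, sigma2 > 0,
            extinction_fraction >= 0, extinction_fraction < 1, steps >= 1)
  structure(list(r1 = r1, r2 = r2, K1 = K1, K2 = K2, alpha = alpha,
                 beta = beta, sigma1 = sigma1, sigma2 = sigma2,
                 extinction_fraction = extinction_fraction,
                 steps = steps, clamp = clamp),
            class = "competition_params")
}

#' @export
print.competition_params <- function(x, ...) {
  cat(sprintf("Lotka-Volterra competition: r = (%g, %g), K = (%g, %g), alpha = %g, beta = %g,\n",
              x$r1, x$r2, x$K1, x$K2, x$alpha, x$beta),
      sprintf(" sigma = (%g, %g), extinction floor = %g K, T = %d\n",
              x$sigma1, x$sigma2, x$extinction_fraction, x$steps))
  invisible(x)
}

#' Deterministic coexistence equilibrium
#'
#' Solves K1 - N1 - alpha N2 = 0, K2 - N2 - beta N1 = 0. With symmetric
#' K and alpha = beta the equilibrium is K / (1 + alpha). Used as the
#' default initial condition, which removes startup transients.
#'
#' @param p A `competition_params` object.
#' @return Named numeric vector `c(N1, N2)`.
#' @export
coexistence_equilibrium <- function(p) {
  det <- 1 - p$alpha * p$beta
  if (det <= 0) abort("no interior equilibrium: alpha * beta >= 1")
  N1 <- (p$K1 - p$alpha * p$K2) / det
  N2 <- (p$K2 - p$beta * p$K1) / det
  if (N1 <= 0 || N2 <= 0) abort("no positive coexistence equilibrium for these parameters")
  c(N1 = N1, N2 = N2)
}

#' One step of the competition map (vectorized over replicates)
#'
#' @param N1,N2 Current densities (numeric vectors of equal length).
#' @param p A `competition_params` object.
#' @param eps1,eps2 Environmental noise draws for this step.
#' @return List with updated `N1`, `N2` (extinction floor applied) and
#'   `clamped`, the count of exponent-argument clamps (0 at the default
#'   parameters).
#' @export
competition_step <- function(N1, N2, p, eps1, eps2) {
  g1 <- p$r1 * (p$K1 - N1 - p$alpha * N2) / p$K1 + p$sigma1 * eps1
  g2 <- p$r2 * (p$K2 - N2 - p$beta * N1) / p$K2 + p$sigma2 * eps2
  clamped <- sum(abs(g1) > p$clamp) + sum(abs(g2) > p$clamp)
  N1 <- N1 * exp(pmin(pmax(g1, -p$clamp), p$clamp))
  N2 <- N2 * exp(pmin(pmax(g2, -p$clamp), p$clamp))
  if (p$extinction_fraction > 0) {
    N1[N1 < p$extinction_fraction * p$K1] <- 0
    N2[N2 < p$extinction_fraction * p$K2] <- 0
  }
  list(N1 = N1, N2 = N2, clamped = clamped)
}

resolve_init <- function(p, init) {
  if (is.numeric(init) && length(init) == 2) return(init)
  switch(match.arg(init, c("equilibrium", "K")),
         equilibrium = coexistence_equilibrium(p),
         K = c(p$K1, p$K2))
}

# Advance nrep replicates through T steps given noise matrices (T x nrep).
# Returns full trajectories as (T+1) x nrep matrices (row 1 = initial).
sim_paths <- function(p, E1, E2, init = "equilibrium") {
  Tn <- nrow(E1)
  nrep <- ncol(E1)
  N0 <- resolve_init(p, init)
  N1 <- matrix(0, Tn + 1, nrep)
  N2 <- matrix(0, Tn + 1, nrep)
  N1[1, ] <- N0[1]
  N2[1, ] <- N0[2]
  n1 <- N1[1, ]
  n2 <- N2[1, ]
  clamped <- 0L
  for (t in seq_len(Tn)) {
    st <- competition_step(n1, n2, p, E1[t, ], E2[t, ])
    n1 <- st$N1
    n2 <- st$N2
    clamped <- clamped + st$clamped
    N1[t + 1, ] <- n1
    N2[t + 1, ] <- n2
  }
  list(N1 = N1, N2 = N2, clamped = clamped)
}

#' Simulate one trajectory of the competition model
#'
#' Runs the model for `p$steps` steps driven by a supplied noise
#' realization (or by noise generated from `spec`). Extinction is
#' absorbing: the extinct flags equal "hit zero at any time up to T",
#' which coincides with being zero at T.
#'
#' @param p A `competition_params` object.
#' @param noise Tibble with `eps1`, `eps2` of length `p$steps` (e.g. from
#'   [generate_noise()]); mutually exclusive with `spec`.
#' @param spec A `noise_spectrum` used to draw the noise when `noise` is
#'   not given. `spec = NULL` with no noise runs the deterministic model.
#' @param seed Seed for noise generation.
#' @param init `"equilibrium"` (default), `"K"`, or numeric length 2.
#' @return Tibble `t` (0..T), `N1`, `N2`; attributes `extinct` (logical
#'   length 2) and `clamped`.
#' @export
simulate_competition <- function(p, noise = NULL, spec = NULL, seed = NULL,
                                 init = "equilibrium") {
  Tn <- p$steps
  if (is.null(noise)) {
    if (is.null(spec)) {
      E1 <- matrix(0, Tn, 1)
      E2 <- matrix(0, Tn, 1)
    } else {
      e <- with_seed_(seed, noise_matrix(spec, Tn, 1))
      E1 <- e$eps1
      E2 <- e$eps2
    }
  } else {
    stopifnot(all(c("eps1", "eps2") %in% names(noise)), nrow(noise) >= Tn)
    E1 <- matrix(noise$eps1[seq_len(Tn)], Tn, 1)
    E2 <- matrix(noise$eps2[seq_len(Tn)], Tn, 1)
  }
  sp <- sim_paths(p, E1, E2, init)
  out <- tibble(t = 0:Tn, N1 = sp$N1[, 1], N2 = sp$N2[, 1])
  attr(out, "extinct") <- c(N1 = sp$N1[Tn + 1, 1] == 0, N2 = sp$N2[Tn + 1, 1] == 0)
  attr(out, "clamped") <- sp$clamped
  out
}

#' Extinction-risk sweep over noise color and competition intensity
#'
#' For every (alpha, slope) cell, draws `n_reps` fresh bivariate noise
#' realizations from the linear spectrum family, simulates `n_reps`
#' replicate trajectories with the absorbing extinction floor, and
#' estimates each species' extinction probability as the fraction of
#' replicates extinct at T, with binomial Monte-Carlo standard errors.
#'
#' @param p Base `competition_params` (its `alpha` is overridden).
#' @param alpha_values Competition intensities to sweep; default
#'   `c(0.25, 0.5, 0.75)`.
#' @param slopes Noise spectral slopes; default 101 values from +2
#'   (bluest) to -2 (reddest).
#' @param n_reps Replicates per cell; default 2000.
#' @param mean_power,cospectrum_fraction Linear-spectrum family
#'   parameters; defaults 0.5 and 0.9.
#' @param seed Master seed; all cells draw from one sequential stream.
#' @param init Initial condition (see [simulate_competition()]).
#' @return Tibble of class `ecots_sweep`: `alpha`, `slope`,
#'   `p_ext_native`, `p_ext_invader`, `se_native`, `se_invader`.
#' @export
extinction_sweep <- function(p = competition_params(),
                             alpha_values = c(0.25, 0.5, 0.75),
                             slopes = seq(2, -2, length.out = 101),
                             n_reps = 2000, mean_power = 0.5,
                             cospectrum_fraction = 0.9, seed = NULL,
                             init = "equilibrium") {
  cells <- tidyr::expand_grid(alpha = alpha_values, slope = slopes)
  res <- with_seed_(seed, {
    purrr::pmap(cells, function(alpha, slope) {
      pa <- p
      pa$alpha <- alpha
      spec <- linear_noise_spec(slope, mean_power, cospectrum_fraction)
      e <- noise_matrix(spec, pa$steps, n_reps)
      sp <- sim_paths(pa, e$eps1, e$eps2, init)
      ex1 <- mean(sp$N1[pa$steps + 1, ] == 0)
      ex2 <- mean(sp$N2[pa$steps + 1, ] == 0)
      tibble(alpha = alpha, slope = slope,
             p_ext_native = ex1, p_ext_invader = ex2,
             se_native = sqrt(ex1 * (1 - ex1) / n_reps),
             se_invader = sqrt(ex2 * (1 - ex2) / n_reps))
    })
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("ecots_sweep", class(out))
  out
}

# vectorized unsmoothed-normalized-spectrum exponents for the columns of a
# data matrix (rows = time); returns one exponent per column
matrix_exponents <- function(M) {
  n <- nrow(M)
  m <- n %/% 2
  Mc <- sweep(M, 2, colMeans(M), "-")
  P <- Mod(mvfft(Mc)[2:(m + 1), , drop = FALSE])^2
  if (n %% 2 == 0) P[m, ] <- P[m, ] / 2
  # drop frequencies with structurally zero power (e.g. the Nyquist
  # ordinate when the target spectrum vanishes there), as in
  # spectral_exponent()
  keep <- apply(P > 0, 1, all)
  P <- P[keep, , drop = FALSE]
  P <- sweep(P, 2, colSums(P), "/")
  lf <- log(((1:m) / n)[keep])
  w <- (lf - mean(lf)) / sum((lf - mean(lf))^2)
  as.numeric(crossprod(w, log(P)))
}

#' Mean spectral exponents of populations and noise along a color sweep
#'
#' For each noise slope, runs `n_reps` replicates with the extinction
#' floor disabled, estimates each replicate's unsmoothed normalized
#' population spectra and noise spectra, computes their spectral
#' exponents, and averages: the population exponent curve shows how the
#' population dynamics redden the environmental color.
#'
#' @inheritParams extinction_sweep
#' @param slopes Noise slopes; default 101 values +2 to -2.
#' @return Tibble: `slope`, `mean_exp_pop`, `mean_exp_noise` (averages
#'   over replicates and over the two species / two noise series).
#' @export
exponent_sweep <- function(p = competition_params(),
                           slopes = seq(2, -2, length.out = 101),
                           n_reps = 2000, mean_power = 0.5,
                           cospectrum_fraction = 0.9, seed = NULL,
                           init = "equilibrium") {
  p$extinction_fraction <- 0
  res <- with_seed_(seed, {
    purrr::map(slopes, function(slope) {
      spec <- linear_noise_spec(slope, mean_power, cospectrum_fraction)
      e <- noise_matrix(spec, p$steps, n_reps)
      sp <- sim_paths(p, e$eps1, e$eps2, init)
      pop <- c(matrix_exponents(sp$N1[-1, , drop = FALSE]),
               matrix_exponents(sp$N2[-1, , drop = FALSE]))
      noi <- c(matrix_exponents(e$eps1), matrix_exponents(e$eps2))
      tibble(slope = slope, mean_exp_pop = mean(pop),
             mean_exp_noise = mean(noi))
    })
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_reps") <- n_reps
  class(out) <- c("ecots_expsweep", class(out))
  out
}

#' Replicate-averaged smoothed normalized spectra and cospectrum
#'
#' Runs `n_reps` replicates of the model without extinction, computes
#' each replicate's smoothed normalized population spectra and
#' cospectrum (normalized to the replicate's own Pearson correlation),
#' and averages them over replicates, alongside the mean unsmoothed
#' spectral exponents of populations and noise.
#'
#' @inheritParams extinction_sweep
#' @param spec A `noise_spectrum` driving all replicates.
#' @param spans Daniell spans for the per-replicate smoothing.
#' @return List of class `ecots_repsummary`: `spectra` (tibble with
#'   `frequency`, `period`, `power1`, `power2`, `cospectrum`),
#'   `exponents` (tibble `quantity`, `mean_exponent`), `n_reps`.
#' @export
replicate_spectral_summary <- function(p = competition_params(), spec,
                                       n_reps = 2000, seed = NULL,
                                       spans = c(5, 7), init = "equilibrium") {
  p$extinction_fraction <- 0
  Tn <- p$steps
  m <- Tn %/% 2
  Sm <- daniell_matrix(m, spans)
  scale <- 2 / (Tn * (Tn - 1))
  out <- with_seed_(seed, {
    e <- noise_matrix(spec, Tn, n_reps)
    sp <- sim_paths(p, e$eps1, e$eps2, init)
    N1 <- sp$N1[-1, , drop = FALSE]
    N2 <- sp$N2[-1, , drop = FALSE]
    fft_pos <- function(M) {
      Mc <- sweep(M, 2, colMeans(M), "-")
      mvfft(Mc)[2:(m + 1), , drop = FALSE]
    }
    X <- fft_pos(N1)
    Y <- fft_pos(N2)
    pw <- function(Z) {
      P <- Mod(Z)^2 * scale
      if (Tn %% 2 == 0) P[m, ] <- P[m, ] / 2
      P <- Sm %*% P
      sweep(P, 2, colSums(P), "/")
    }
    P1 <- pw(X)
    P2 <- pw(Y)
    CO <- Re(X * Conj(Y)) * scale
    if (Tn %% 2 == 0) CO[m, ] <- CO[m, ] / 2
    CO <- Sm %*% CO
    sds <- sqrt(apply(N1, 2, var) * apply(N2, 2, var))
    CO <- sweep(CO, 2, sds, "/")
    r <- vapply(seq_len(n_reps), function(j) cor(N1[, j], N2[, j]), numeric(1))
    s <- colSums(CO)
    ok <- abs(s) > 1e-12
    CO[, ok] <- sweep(CO[, ok, drop = FALSE], 2, r[ok] / s[ok], "*")
    list(
      spectra = tibble(frequency = (1:m) / Tn, period = Tn / (1:m),
                       power1 = rowMeans(P1), power2 = rowMeans(P2),
                       cospectrum = rowMeans(CO)),
      exponents = tibble(
        quantity = c("population", "noise"),
        mean_exponent = c(mean(c(matrix_exponents(N1), matrix_exponents(N2))),
                          mean(c(matrix_exponents(e$eps1), matrix_exponents(e$eps2))))),
      n_reps = n_reps)
  })
  structure(out, class = "ecots_repsummary")
}
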