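test_that("carrying capacity and the coexistence point are fixed points", {
  p0 <- competition_params(alpha = 0, beta = 0, extinction_fraction = 0)
  st <- competition_step(50, 50, p0, 0, 0)
  expect_equal(st$N1, 50)
  expect_equal(st$N2, 50)
  p <- competition_params(alpha = 0.25, beta = 0.25, extinction_fraction = 0)
  eq <- coexistence_equilibrium(p)
  expect_equal(unname(eq), c(40, 40)) # K / (1 + alpha)
  st2 <- competition_step(40, 40, p, 0, 0)
  expect_equal(st2$N1, 40)
  expect_equal(st2$N2, 40)
})

test_that("asymmetric equilibrium solves the two linear equations", {
  p <- competition_params(alpha = 0.75, beta = 0.25)
  eq <- coexistence_equilibrium(p)
  expect_equal(p$K1 - eq[["N1"]] - p$alpha * eq[["N2"]], 0, tolerance = 1e-12)
  expect_equal(p$K2 - eq[["N2"]] - p$beta * eq[["N1"]], 0, tolerance = 1e-12)
})

test_that("populations below 5% of K are absorbed at zero", {
  p <- competition_params()
  st <- competition_step(1.5, 50, p, 0, 0) # 1.5 * exp(~0.29) ~ 2.0 < 2.5
  expect_equal(st$N1, 0)
  # zero is absorbing through further steps
  st2 <- competition_step(st$N1, st$N2, p, 1, 1)
  expect_equal(st2$N1, 0)
})

test_that("the deterministic map converges monotonically from K to the equilibrium", {
  p <- competition_params(alpha = 0.25, beta = 0.25, extinction_fraction = 0)
  tr <- simulate_competition(p, init = "K")
  expect_equal(tr$N1[1], 50)
  expect_true(all(diff(tr$N1) <= 1e-12)) # undercompensatory: no overshoot
  expect_equal(tr$N1[nrow(tr)], 40, tolerance = 1e-6)
  expect_equal(tr$N1, tr$N2)
})

test_that("stochastic trajectories match the naive scalar oracle bit for bit", {
  p <- competition_params(alpha = 0.5)
  eps <- generate_noise(linear_noise_spec(-1), 100, seed = 33)
  tr <- simulate_competition(p, noise = eps)
  orc <- lv_oracle(p, coexistence_equilibrium(p), eps$eps1, eps$eps2)
  expect_identical(tr$N1, orc$N1)
  expect_identical(tr$N2, orc$N2)
})

test_that("no trajectory resurrects after extinction", {
  withr::with_seed(34, {
    p <- competition_params(alpha = 0.75)
    for (i in 1:20) {
      tr <- simulate_competition(p, spec = linear_noise_spec(-2))
      z <- which(tr$N1 == 0)
      if (length(z) > 0) expect_true(all(tr$N1[z[1]:nrow(tr)] == 0))
    }
  })
})

test_that("symmetric species have exchangeable extinction risks", {
  sw <- extinction_sweep(alpha_values = 0.25, slopes = -2, n_reps = 2000, seed = 35)
  se <- sqrt(sw$p_ext_native * (1 - sw$p_ext_native) / 2000)
  expect_lt(abs(sw$p_ext_native - sw$p_ext_invader), 5 * se * sqrt(2))
})

test_that("extinction risk rises with competition intensity and with reddening", {
  sw <- extinction_sweep(alpha_values = c(0.25, 0.75), slopes = c(2, -2),
                         n_reps = 1000, seed = 36)
  at <- function(a, s) sw$p_ext_native[sw$alpha == a & sw$slope == s]
  expect_gte(at(0.75, -2), at(0.25, -2)) # monotone in alpha
  expect_gte(at(0.75, -2), at(0.75, 2))  # monotone blue -> red
  expect_gte(at(0.25, -2), at(0.25, 2))
  expect_lt(at(0.25, 2), 0.10)           # bluest symmetric case stays small
})

test_that("population dynamics redden white environmental noise", {
  rs <- replicate_spectral_summary(competition_params(), linear_noise_spec(0),
                                   n_reps = 300, seed = 37)
  sp <- rs$spectra
  dec <- floor(nrow(sp) / 10)
  expect_gt(mean(sp$power1[1:dec]), mean(sp$power1[(nrow(sp) - dec + 1):nrow(sp)]))
  # exchangeable species -> equal mean spectra up to Monte-Carlo noise
  expect_equal(sp$power1, sp$power2, tolerance = 0.1)
  ex <- rs$exponents
  expect_lt(ex$mean_exponent[ex$quantity == "population"], 0)
  expect_lt(abs(ex$mean_exponent[ex$quantity == "noise"]), 0.1)
})

test_that("mean exponents decrease monotonically along the blue-to-red sweep", {
  es <- exponent_sweep(slopes = seq(2, -2, length.out = 5), n_reps = 300, seed = 38)
  expect_true(all(diff(es$mean_exp_pop) < 0.05))   # slopes ordered +2 -> -2
  expect_true(all(diff(es$mean_exp_noise) < 0.05))
  expect_lt(es$mean_exp_pop[1], 0) # negative already under the bluest noise
})

test_that("overflow clamping is never triggered at the reference parameters", {
  tr <- simulate_competition(competition_params(), spec = linear_noise_spec(-2),
                             seed = 39)
  expect_equal(attr(tr, "clamped"), 0)
})
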