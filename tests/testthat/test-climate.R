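test_that("quadratic detrending standardizes residuals and rejects exact quadratics", {
  withr::with_seed(50, {
    t <- 1:100
    x <- rnorm(100)
    r <- quadratic_detrend(x)
    expect_equal(sum(r^2), 100 - 3, tolerance = 1e-9) # sd 1 with ddof 3
    expect_equal(mean(r), 0, tolerance = 1e-10)
    expect_gt(cor(r, scale(x)[, 1]), 0.95) # projection removes only 3 dof
    expect_error(quadratic_detrend(2 + 0.5 * t - 0.01 * t^2), "zero residual")
    # invariance: adding any quadratic trend changes nothing
    r2 <- quadratic_detrend(x + 5 - 3 * t + 0.2 * t^2)
    expect_equal(r2, r, tolerance = 1e-9)
  })
})

test_that("era exponents recover prescribed white and red residual targets", {
  # generator round trip: target 0 (white after detrending) -> mean ~ 0
  st <- synth_station_network(n_stations = 200, era_slopes = c(0, 0, 0, 0),
                              spatial_range_km = 0.001, seed = 51)
  ee <- era_exponents(st)
  mm <- tapply(ee$exponent, ee$era, mean)
  expect_true(all(abs(mm) < 0.12))
  # raw red innovations in the last era read as a negative mean exponent
  st2 <- synth_station_network(n_stations = 100, era_slopes = c(0, 0, 0, -1.5),
                               calibrate = FALSE, spatial_range_km = 0.001,
                               seed = 52)
  mm2 <- tapply(era_exponents(st2)$exponent, era_exponents(st2)$era, mean)
  expect_lt(mm2[4], -0.3)
  expect_gt(mm2[4] - mm2[1], -Inf) # eras independent, sanity
})

test_that("stations with missing era years are dropped, not imputed", {
  st <- synth_station_network(n_stations = 12, seed = 53)
  st <- st[!(st$station_id == "S0001" & st$year == 1920), ]
  ee <- era_exponents(st)
  expect_equal(attr(ee, "n_dropped"), 1L)
  expect_equal(sum(ee$station_id == "S0001"), 3) # lost only the 1915-1939 era
})

test_that("independent station values give an effective sample size of n", {
  withr::with_seed(54, {
    lat <- runif(120, 30, 48)
    lon <- runif(120, -120, -75)
    ne <- effective_sample_size(rnorm(120), lat, lon)
    expect_gt(as.numeric(ne), 0.9 * 120)
  })
})

test_that("a smooth continental gradient collapses the effective sample size", {
  withr::with_seed(55, {
    lat <- runif(100, 30, 48)
    lon <- runif(100, -120, -75)
    v <- lat + rnorm(100, 0, 0.05) # one big spatial feature
    ne <- as.numeric(effective_sample_size(v, lat, lon))
    expect_lt(ne, 15)
  })
})

test_that("the estimator tracks the variance-of-mean oracle for a Gaussian field", {
  withr::with_seed(56, {
    n <- 200
    lat <- runif(n, 30, 48)
    lon <- runif(n, -120, -75)
    D <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
    # moderate range: the regime where one realization carries enough
    # information about the correlogram
    C <- exp(-D / (max(D) / 16))
    R <- chol(C + diag(1e-8, n))
    oracle <- n^2 / sum(C)
    est <- replicate(12, {
      v <- as.vector(crossprod(R, rnorm(n)))
      as.numeric(effective_sample_size(v, lat, lon))
    })
    expect_lt(abs(mean(est) - oracle) / oracle, 0.35)
    # very strong correlation: detected as a large reduction even though
    # the exact level is unidentifiable from one realization
    C4 <- exp(-D / (max(D) / 4))
    R4 <- chol(C4 + diag(1e-8, n))
    est4 <- replicate(8, {
      v <- as.vector(crossprod(R4, rnorm(n)))
      as.numeric(effective_sample_size(v, lat, lon))
    })
    expect_lt(median(est4), n / 5)
  })
})

test_that("identical paired fields give t = 0 and p = 1", {
  withr::with_seed(57, {
    lat <- runif(50, 30, 48)
    lon <- runif(50, -120, -75)
    e <- rnorm(50)
    res <- corrected_paired_ttest(e, e, lat, lon)
    expect_equal(res$t, 0)
    expect_equal(res$p_value, 1)
    expect_equal(res$p_adjusted, 1)
  })
})

test_that("a -0.5 shift across independent stations is strongly significant", {
  withr::with_seed(58, {
    n <- 200
    lat <- runif(n, 30, 48)
    lon <- runif(n, -120, -75)
    a <- rnorm(n, 0.4, 0.5)
    b <- rnorm(n, -0.1, 0.5)
    res <- corrected_paired_ttest(a, b, lat, lon)
    expect_lt(res$p_adjusted, 0.01)
    expect_equal(res$mean_diff, -0.5, tolerance = 0.2)
  })
})

test_that("stronger spatial correlation weakens the paired test monotonically", {
  withr::with_seed(59, {
    n <- 150
    lat <- runif(n, 30, 48)
    lon <- runif(n, -120, -75)
    D <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
    R <- chol(exp(-D / (max(D) / 6)) + diag(1e-8, n))
    shift <- -0.25
    noise <- as.vector(crossprod(R, rnorm(n))) * 0.5
    a <- rnorm(n, 0, 0.5)
    b_ind <- a + shift + rnorm(n, 0, 0.2)
    b_cor <- a + shift + noise
    p_ind <- corrected_paired_ttest(a, b_ind, lat, lon)
    p_cor <- corrected_paired_ttest(a, b_cor, lat, lon)
    expect_lt(p_cor$n_eff, p_ind$n_eff)
    expect_gt(p_cor$p_value, p_ind$p_value)
  })
})
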