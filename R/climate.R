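#' Quadratic detrend with standardized residuals
#'
#' Removes a least-squares quadratic trend (value ~ 1 + t + t^2) and
#' divides the residuals by their standard deviation (ddof = 3 for the
#' fitted parameters). Spectral exponents of the residuals are invariant
#' to the standardization constant; it only fixes the residual scale.
#'
#' @param x Numeric vector, length >= 5.
#' @return Standardized residuals: mean 0, sd computed with ddof 3 equal
#'   to 1.
#' @export
quadratic_detrend <- function(x) {
  n <- length(x)
  if (n < 5) abort("need at least 5 observations to fit a quadratic trend")
  t <- seq_len(n)
  r <- lm(x ~ t + I(t^2))$residuals
  s2 <- sum(r^2) / (n - 3)
  if (s2 < 1e-20 * max(1, mean(x^2))) abort("zero residual variance after quadratic detrend")
  unname(r / sqrt(s2))
}

default_eras <- function() {
  list(c(1915, 1939), c(1940, 1964), c(1965, 1989), c(1990, 2014))
}

era_label <- function(era) paste0(era[1], "-", era[2])

#' Era-wise spectral exponents for a station network
#'
#' Splits each station's annual series into eras (by default four
#' 25-year spans of 1915-2014), quadratically detrends and standardizes
#' each station-era segment, computes its unsmoothed spectrum, and
#' estimates the spectral exponent. Stations missing any year of an era
#' are dropped from that era (no imputation).
#'
#' @param stations Data frame with columns `station_id`, `lat`, `lon`,
#'   `year`, `mean_temp`.
#' @param eras List of `c(first_year, last_year)` pairs.
#' @return Tibble with `station_id`, `lat`, `lon`, `era`, `exponent`;
#'   attribute `n_dropped` counts dropped station-era segments.
#' @export
era_exponents <- function(stations, eras = default_eras()) {
  need <- c("station_id", "lat", "lon", "year", "mean_temp")
  if (!all(need %in% names(stations)))
    abort(paste("stations must have columns:", paste(need, collapse = ", ")))
  dropped <- 0L
  rows <- list()
  by_st <- split(stations, stations$station_id)
  for (st in by_st) {
    st <- st[order(st$year), ]
    for (era in eras) {
      yrs <- era[1]:era[2]
      seg <- st$mean_temp[match(yrs, st$year)]
      if (anyNA(seg)) {
        dropped <- dropped + 1L
        next
      }
      resid <- quadratic_detrend(seg)
      p <- periodogram_core(resid, demean = TRUE)
      f <- fourier_freqs(length(resid))
      rows[[length(rows) + 1L]] <- tibble(
        station_id = st$station_id[1], lat = st$lat[1], lon = st$lon[1],
        era = era_label(era), exponent = exponent_core(p, f))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$era <- factor(out$era, levels = vapply(eras, era_label, character(1)))
  attr(out, "n_dropped") <- dropped
  out
}

#' Effective sample size under spatial autocorrelation
#'
#' Estimates how many effectively independent observations a spatially
#' autocorrelated field of station values contains, in the spirit of the
#' Clifford-Dutilleul correction for tests on spatial data. Moran-type
#' spatial autocorrelations are estimated in `n_classes` equal-pair-count
#' great-circle-distance bins; an exponential correlogram model
#' rho(d) = rho0 exp(-d / phi) is then fitted to the class correlations
#' by pair-count-weighted least squares and summed over every station
#' pair, giving n_eff = n^2 / sum_ij rho_model(d_ij). The model fit
#' matters: raw class correlations in classes whose true correlation is
#' near zero contribute pure noise of variance O(N_k), and a weak but
#' spatially extensive correlation tail -- statistically invisible class
#' by class -- still inflates the variance of the field mean. Because
#' centering on the sample mean depresses every class correlation by
#' about 1/n_eff (the mean absorbs the common component), the fit and
#' the implied n_eff are iterated to a bias-corrected fixed point. The
#' result is clamped to \[2, n\].
#'
#' @param values Numeric vector of per-station values (e.g. paired
#'   exponent differences).
#' @param lat,lon Station coordinates in decimal degrees.
#' @param n_classes Number of distance classes; default 12.
#' @return Scalar effective sample size with attribute `classes`
#'   (tibble of class distances, pair counts and autocorrelations) and
#'   attribute `model` (fitted rho0 and phi).
#' @export
effective_sample_size <- function(values, lat, lon, n_classes = 12) {
  n <- length(values)
  stopifnot(length(lat) == n, length(lon) == n)
  if (n < 10) abort("need at least 10 stations")
  D <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  dmax <- max(D)
  if (dmax <= 0) abort("degenerate geometry: all stations co-located")
  iu <- which(upper.tri(D))
  d <- D[iu]
  ii <- row(D)[iu]
  jj <- col(D)[iu]
  v <- values - mean(values)
  denom <- sum(v^2) / n
  if (denom == 0) abort("values have zero variance")
  br <- unique(quantile(d, probs = seq(0, 1, length.out = n_classes + 1),
                        names = FALSE))
  cls <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  cross <- v[ii] * v[jj]
  Nk <- tabulate(cls, nbins = length(br) - 1)
  rho <- vapply(seq_along(Nk), function(k) {
    if (Nk[k] == 0) return(0)
    mean(cross[cls == k]) / denom
  }, numeric(1))
  dbar <- vapply(seq_along(Nk), function(k) {
    if (Nk[k] == 0) return(NA_real_)
    mean(d[cls == k])
  }, numeric(1))
  ok <- Nk > 0
  # weighted LS fit of rho0 * exp(-dbar/phi) on a phi grid (rho0 has a
  # closed form given phi), iterated with the centering-bias correction
  phi_grid <- exp(seq(log(dmax / 200), log(dmax), length.out = 40))
  fit_model <- function(target) {
    best <- c(rho0 = 0, phi = phi_grid[1], sse = Inf)
    for (phi in phi_grid) {
      b <- exp(-dbar[ok] / phi)
      r0 <- sum(Nk[ok] * b * target[ok]) / sum(Nk[ok] * b^2)
      r0 <- min(max(r0, 0), 1)
      sse <- sum(Nk[ok] * (target[ok] - r0 * b)^2)
      if (sse < best["sse"]) best <- c(rho0 = r0, phi = phi, sse = sse)
    }
    best
  }
  # evidence gate: without a significant nearest-class correlation there
  # is no basis for a spatial model, and fitting one to noise would
  # spuriously deflate n_eff for independent fields
  if (!ok[1] || rho[1] <= 2 / sqrt(Nk[1])) {
    n_eff <- as.numeric(n)
    mod <- c(rho0 = 0, phi = NA_real_)
  } else {
    neff_from <- function(target) {
      fit <- fit_model(target)
      pair_sum <- fit["rho0"] * sum(exp(-d / fit["phi"]))
      list(n_eff = min(max(n^2 / (n + 2 * pair_sum), 2), n),
           mod = fit[c("rho0", "phi")])
    }
    # initial fit on the raw class correlations, then one de-biased
    # refit (a full fixed point is unstable: the bias term feeds back)
    f0 <- neff_from(rho)
    target <- pmin(1, rho * (1 - 1 / f0$n_eff) + 1 / f0$n_eff)
    f1 <- neff_from(target)
    n_eff <- unname(f1$n_eff)
    mod <- f1$mod
  }
  attr(n_eff, "classes") <- tibble(
    class = seq_along(Nk),
    mean_distance_km = dbar / 1000,
    n_pairs = Nk, rho = rho)
  attr(n_eff, "model") <- c(rho0 = unname(mod[1]), phi_km = unname(mod[2]) / 1000)
  n_eff
}

#' Paired t-test corrected for spatial autocorrelation
#'
#' A paired t-test on per-station differences whose standard error and
#' degrees of freedom use the effective sample size of the difference
#' field instead of the raw station count, with a Bonferroni adjustment
#' across `n_comparisons` planned comparisons.
#'
#' @param exp_a,exp_b Paired per-station values (e.g. spectral exponents
#'   in two eras); the test is on `exp_b - exp_a`.
#' @param lat,lon Station coordinates.
#' @param n_comparisons Bonferroni multiplier; default 3 (the three
#'   consecutive-era comparisons).
#' @param n_classes Distance classes for [effective_sample_size()].
#' @return One-row tibble: `mean_diff`, `n`, `n_eff`, `t`, `df`,
#'   `p_value`, `p_adjusted`.
#' @export
corrected_paired_ttest <- function(exp_a, exp_b, lat, lon,
                                   n_comparisons = 3, n_classes = 12) {
  stopifnot(length(exp_a) == length(exp_b))
  d <- exp_b - exp_a
  n <- length(d)
  if (sd(d) == 0) {
    return(tibble(mean_diff = 0, n = n, n_eff = as.numeric(n), t = 0,
                  df = n - 1, p_value = 1, p_adjusted = 1))
  }
  n_eff <- effective_sample_size(d, lat, lon, n_classes)
  tval <- mean(d) / (sd(d) / sqrt(n_eff))
  df <- n_eff - 1
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  tibble(mean_diff = mean(d), n = n, n_eff = as.numeric(n_eff),
         t = tval, df = df, p_value = p,
         p_adjusted = min(1, n_comparisons * p))
}

#' Consecutive-era shift tests for an era exponent table
#'
#' Runs the spatially corrected paired t-test for every pair of
#' consecutive eras in an [era_exponents()] table, Bonferroni-adjusting
#' across the comparisons.
#'
#' @param era_tab Output of [era_exponents()].
#' @return Tibble, one row per consecutive-era comparison, with an
#'   `eras` label column plus the [corrected_paired_ttest()] columns.
#' @export
era_shift_tests <- function(era_tab) {
  levs <- levels(era_tab$era)
  ncomp <- length(levs) - 1
  res <- purrr::map(seq_len(ncomp), function(i) {
    a <- era_tab[era_tab$era == levs[i], ]
    b <- era_tab[era_tab$era == levs[i + 1], ]
    common <- intersect(a$station_id, b$station_id)
    a <- a[match(common, a$station_id), ]
    b <- b[match(common, b$station_id), ]
    dplyr::bind_cols(
      tibble(eras = paste(levs[i], "vs", levs[i + 1])),
      corrected_paired_ttest(a$exponent, b$exponent, a$lat, a$lon,
                             n_comparisons = ncomp))
  })
  dplyr::bind_rows(res)
}
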