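#' Harmonic regression with a nested-model test for the shorter cycle
#'
#' Fits sine and cosine regressors at each requested period plus an
#' intercept by ordinary least squares, and compares the full model to
#' one containing only the first period's harmonics with a nested-model
#' F test. With the default periods (12, 6) on monthly data this asks
#' whether a semiannual cycle improves on an annual-only seasonal model.
#'
#' @param data Data frame with the series.
#' @param value Column to fit (tidy-eval).
#' @param periods Harmonic periods in sampling units, longest first;
#'   default `c(12, 6)`.
#' @param dt Sampling interval.
#' @return An object of class `ecots_harmonic`: use [tidy()] for the
#'   per-period amplitude/phase table and [glance()] for fit summaries
#'   (RSS of full and reduced models, F statistic, p value).
#' @export
harmonic_fit <- function(data, value, periods = c(12, 6), dt = 1) {
  x <- pull_num(data, {{ value }})
  n <- length(x)
  if (n < 2 * max(periods) / dt) abort("series too short for harmonic fitting")
  t <- seq_len(n) * dt
  reg <- lapply(periods, function(p)
    cbind(sin(2 * pi * t / p), cos(2 * pi * t / p)))
  Xfull <- do.call(cbind, reg)
  colnames(Xfull) <- paste0(rep(c("sin", "cos"), length(periods)),
                            rep(periods, each = 2))
  fit_full <- lm(x ~ Xfull)
  fit_red <- lm(x ~ reg[[1]])
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  df_extra <- 2 * (length(periods) - 1)
  df_res <- n - 1 - 2 * length(periods)
  Fstat <- ((rss_red - rss_full) / df_extra) / (rss_full / df_res)
  pval <- pf(Fstat, df_extra, df_res, lower.tail = FALSE)
  cf <- coef(fit_full)
  amp <- phase <- numeric(length(periods))
  for (i in seq_along(periods)) {
    a <- cf[2 * i]      # sin coefficient
    b <- cf[2 * i + 1]  # cos coefficient
    amp[i] <- sqrt(a^2 + b^2)
    phase[i] <- atan2(a, b)
  }
  structure(
    list(periods = periods, amplitude = amp, phase = phase,
         intercept = unname(cf[1]), rss_full = rss_full,
         rss_reduced = rss_red, f_statistic = Fstat, p_value = pval,
         df = c(df_extra, df_res), n = n, fit = fit_full),
    class = "ecots_harmonic")
}

#' @export
print.ecots_harmonic <- function(x, ...) {
  cat("Harmonic fit: periods", paste(x$periods, collapse = ", "),
      sprintf("| intercept %.3f\n", x$intercept))
  print(tidy(x))
  cat(sprintf("Shorter-cycle F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.ecots_harmonic <- function(x, ...) {
  tibble(period = x$periods, amplitude = x$amplitude, phase = x$phase)
}

#' @export
glance.ecots_harmonic <- function(x, ...) {
  tibble(rss_full = x$rss_full, rss_reduced = x$rss_reduced,
         f_statistic = x$f_statistic, p_value = x$p_value, n = x$n)
}
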