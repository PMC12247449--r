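# Shared fixtures, built in code.

# Small, fast configuration for structural tests (2 windows).
tiny_config <- function(..., seed = 42L) {
  synthetic_config(n_lat = 2, n_lon = 3, years = c(1998, 2018), seed = seed, ...)
}

zero_noise <- c(yield = 0, fco2 = 0, fn2o = 0, fch4 = 0)

# Yield held exactly constant so GHGI is linear in the extreme-day counts.
linear_response_config <- function(..., noise_sd_response =
                                     c(yield = 0, fco2 = 6, fn2o = 0.02,
                                       fch4 = 0.002), seed = 1L) {
  slopes <- default_driver_slopes()
  slopes$slope[slopes$variable == "yield"] <- 0
  synthetic_config(
    beta_yield = c(hc = 0, dc = 0, cdhc = 0), yield_trend = 0,
    driver_slopes = slopes, noise_sd_response = noise_sd_response,
    seed = seed, ...
  )
}

# Daily dates of one year.
year_dates <- function(year) {
  seq(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-12-31", year)),
      by = "day")
}

# Naive day-by-day counting oracle over the Mar 1 - Sep 30 window.
oracle_counts <- function(dates, tmax, ai, year,
                          heat_threshold = 30, aridity_threshold = 0.2) {
  hc <- 0L; dc <- 0L; cdhc <- 0L
  for (i in seq_along(dates)) {
    lt <- as.POSIXlt(dates[i])
    if (lt$year + 1900L != year || !((lt$mon + 1L) %in% 3:9)) next
    hot <- tmax[i] > heat_threshold
    dry <- !is.na(ai[i]) && ai[i] < aridity_threshold
    if (hot) hc <- hc + 1L
    if (dry) dc <- dc + 1L
    if (hot && dry) cdhc <- cdhc + 1L
  }
  c(hc = hc, dc = dc, cdhc = cdhc)
}

# Closed-form windowed Pearson correlation between one detrended index series
# and the linear-response GHGI implied by injected coefficients: covariance
# algebra on the index matrix plus the known noise variance, never touching the
# generated responses.
implied_r_series <- function(hc, dc, cdhc, years, weights, noise_var, window) {
  xm <- cbind(hc = detrend_linear(hc, years), dc = detrend_linear(dc, years),
              cdhc = detrend_linear(cdhc, years))
  sapply(seq_len(3), function(j) {
    vapply(window:length(years), function(e) {
      w <- xm[(e - window + 1):e, , drop = FALSE]
      sig <- stats::cov(w)
      num <- sum(sig[j, ] * weights)
      den <- sqrt(sig[j, j] * (drop(t(weights) %*% sig %*% weights) + noise_var))
      if (den <= 0) NA_real_ else num / den
    }, numeric(1))
  })
}

# CO2-equivalent per-extreme-day weights (kg CO2-eq/ha per day) implied by a
# configuration for a given cellwise CO2 multiplier.
implied_eghg_weights <- function(cfg, co2_mult = 1) {
  10 * (co2_mult * cfg$beta_fco2 * 44 / 12 +
          cfg$beta_fn2o * 44 / 28 * 273 +
          cfg$beta_fch4 * 16 / 12 * 27)
}

implied_eghg_noise_var <- function(cfg) {
  s <- cfg$noise_sd_response
  100 * ((s[["fco2"]] * 44 / 12)^2 + (s[["fn2o"]] * 44 / 28 * 273)^2 +
           (s[["fch4"]] * 16 / 12 * 27)^2)
}
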