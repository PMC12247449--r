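test_that("linear detrending removes exactly the OLS line", {
  t <- 1:30
  expect_equal(detrend_linear(3 + 2 * t, t), rep(0, 30), tolerance = 1e-10)
  # y = 2t + sin(t): residuals equal sin(t) minus its own OLS line
  y <- 2 * t + sin(t)
  fit <- lm(sin(t) ~ t)
  expect_equal(detrend_linear(y, t), unname(residuals(fit)), tolerance = 1e-10)
  withr::local_seed(3)
  r <- detrend_linear(rnorm(40))
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(coef(lm(r ~ I(1:40)))[2]), 1e-10)
  expect_equal(detrend_linear(rep(5, 10)), rep(0, 10))
  # missing values stay missing and do not bias the fit
  y2 <- c(1, NA, 3, 4, 5)
  out <- detrend_linear(y2, 1:5)
  expect_true(is.na(out[2]) && !anyNA(out[-2]))
})

test_that("moving-window correlation equals direct slicing for all methods", {
  withr::local_seed(11)
  for (i in 1:50) {
    x <- rnorm(59)
    y <- 0.4 * x + rnorm(59)
    for (m in c("pearson", "kendall", "spearman")) {
      got <- moving_window_correlation(x, y, years = 1960:2018, window = 20,
                                       method = m)
      expect_equal(nrow(got), 40)
      expect_equal(got$window_end_year, 1979:2018)
      want <- vapply(20:59, function(e) {
        cor(x[(e - 19):e], y[(e - 19):e], method = m)
      }, numeric(1))
      expect_equal(got$r, want, tolerance = 1e-12)
    }
  }
})

test_that("moving-window correlation handles exact coupling, nulls and guards", {
  x <- rnorm(40)
  expect_equal(moving_window_correlation(x, 2 * x + 1, window = 10)$r,
               rep(1, 31))
  expect_equal(moving_window_correlation(x, -x, window = 10)$r, rep(-1, 31))
  # method agreement on monotone linear data
  for (m in c("pearson", "kendall", "spearman")) {
    expect_equal(moving_window_correlation(1:30, 2 * (1:30), window = 10,
                                           method = m)$r,
                 rep(1, 21))
  }
  # independence: mean windowed R near zero across many simulations
  withr::local_seed(5)
  rbar <- mean(replicate(1000, cor(rnorm(20), rnorm(20))))
  expect_lt(abs(rbar), 3 / sqrt(20))
  # zero-variance and NA windows are missing, never fabricated
  xz <- c(rep(1, 10), rnorm(10))
  got <- moving_window_correlation(xz, rnorm(20), window = 5)
  expect_true(anyNA(got$r))
  xn <- rnorm(20); xn[7] <- NA
  got2 <- moving_window_correlation(xn, rnorm(20), window = 5)
  expect_true(all(is.na(got2$r[3:7]))) # every window touching the NA
  expect_true(!anyNA(got2$r[8:16]))
  expect_error(moving_window_correlation(x, x, window = 2),
               class = "edhwheat_input_error")
  expect_error(moving_window_correlation(x, x, window = 41),
               class = "edhwheat_input_error")
})

test_that("gridded sensitivity equals a per-cell hand computation", {
  cfg <- tiny_config()
  edh <- compute_edh_field(generate_daily_climate(cfg))
  resp <- ghg_intensity(generate_scenario_outputs(edh, cfg, "S2"))
  sens <- edh_sensitivity(edh, resp, window = 20)
  expect_s3_class(sens, "edh_sensitivity")
  years <- sort(unique(edh$year))
  n_windows <- length(years) - 20 + 1
  expect_equal(nrow(sens), length(unique(edh$cell)) * 3 * 3 * n_windows)
  expect_true(all(abs(sens$r) <= 1, na.rm = TRUE))

  for (probe_cell in c(2L, 5L)) {
    e <- edh[edh$cell == probe_cell, ]
    g <- resp[resp$cell == probe_cell, ]
    x <- detrend_linear(e$dc, e$year)
    y <- detrend_linear(g$ghgi, g$year)
    want <- vapply(20:length(years), function(e_) {
      cor(x[(e_ - 19):e_], y[(e_ - 19):e_])
    }, numeric(1))
    got <- sens[sens$cell == probe_cell & sens$edh_index == "dc" &
                  sens$response == "ghgi", ]
    expect_equal(got$r, want, tolerance = 1e-10)
  }
})

test_that("masked response years never silently enter a window", {
  cfg <- tiny_config()
  edh <- compute_edh_field(generate_daily_climate(cfg))
  resp <- ghg_intensity(generate_scenario_outputs(edh, cfg, "S2"))
  resp$ghgi[resp$cell == 1 & resp$year == 2005] <- NA
  sens <- edh_sensitivity(edh, resp, window = 20)
  hit <- sens[sens$cell == 1 & sens$response == "ghgi", ]
  touching <- hit$window_end_year >= 2005
  expect_true(all(is.na(hit$r[touching])))
  expect_true(all(!is.na(hit$r[!touching])))
  # other cells unaffected
  expect_true(!anyNA(sens$r[sens$cell != 1 & sens$response == "ghgi"]))
})

test_that("OLS trend of a sensitivity series behaves at the edges", {
  flat <- grid_sensitivity_trend(rep(0.3, 20))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  exact <- grid_sensitivity_trend(0.01 * (1:20))
  expect_equal(exact$slope, 0.01, tolerance = 1e-12)
  expect_equal(exact$p_value, 0)
  withr::local_seed(9)
  drift <- 0.005 * (1:40) + rnorm(40, 0, 0.02)
  got <- grid_sensitivity_trend(drift, 1979:2018)
  want <- summary(lm(drift ~ I(1979:2018)))
  expect_equal(got$slope, coef(want)[2, 1], tolerance = 1e-12)
  expect_equal(got$p_value, coef(want)[2, 4], tolerance = 1e-12)
  expect_equal(tidy(got)$estimate, got$slope)
})

test_that("Mann-Kendall statistic matches brute force with tie correction", {
  expect_error(mann_kendall_trend(c(1, 2)), class = "edhwheat_input_error")
  # strictly increasing: all pairs concordant
  n <- 25
  up <- mann_kendall_trend(seq_len(n) + 0.1)
  expect_equal(up$statistic, n * (n - 1) / 2)
  expect_lt(up$p_value, 1e-6)
  expect_equal(up$slope, 1) # Sen slope of the unit ramp
  # all equal: S = 0, p = 1
  flat <- mann_kendall_trend(rep(2, 12))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # random tied series versus an independent pair-loop oracle
  withr::local_seed(21)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE) # heavy ties
    s <- 0
    for (a in 1:14) for (b in (a + 1):15) s <- s + sign(x[b] - x[a])
    got <- mann_kendall_trend(x)
    expect_equal(got$statistic, s)
    n_ <- 15
    ties <- table(x)
    vs <- (n_ * (n_ - 1) * (2 * n_ + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (s > 0) (s - 1) / sqrt(vs) else if (s < 0) (s + 1) / sqrt(vs) else 0
    expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
})

test_that("cross-combination uncertainty follows SE = s / sqrt(n)", {
  base <- tidyr::expand_grid(cell = 1:2, lat = 0, lon = 0,
                             window_end_year = 2000:2001,
                             edh_index = "hc", response = "ghgi")
  mk <- function(r, m, v) dplyr::mutate(base, method = m, dataset_variant = v,
                                        r = r)
  # identical fields: zero spread
  same <- uncertainty_across_combinations(list(mk(0.2, "pearson", "a"),
                                               mk(0.2, "kendall", "a")))
  expect_true(all(same$s == 0) && all(same$se == 0))
  # hand case: r = 0.1 and 0.3
  two <- uncertainty_across_combinations(list(mk(0.1, "pearson", "a"),
                                              mk(0.3, "kendall", "a")))
  expect_equal(two$mean_r, rep(0.2, 4))
  expect_equal(two$s, rep(sd(c(0.1, 0.3)), 4), tolerance = 1e-12)
  expect_equal(two$se, two$s / sqrt(2))
  # n = 9 combinations: SE = s / 3
  combos <- tidyr::expand_grid(m = c("pearson", "kendall", "spearman"),
                               v = c("a", "b", "c"))
  nine <- uncertainty_across_combinations(
    purrr::pmap(list(combos$m, combos$v, seq(0.1, 0.9, by = 0.1)),
                function(m, v, r) mk(r, m, v))
  )
  expect_equal(nine$n, rep(9L, 4))
  expect_equal(nine$se, nine$s / 3)
  expect_error(uncertainty_across_combinations(mk(0.1, "pearson", "a")),
               class = "edhwheat_input_error")
})

test_that("regional summary medians and shares match brute force", {
  withr::local_seed(2)
  cfg <- tiny_config()
  edh <- compute_edh_field(generate_daily_climate(cfg))
  resp <- ghg_intensity(generate_scenario_outputs(edh, cfg, "S2"))
  sens <- edh_sensitivity(edh, resp, window = 20)
  reg <- regional_summary(sens)
  one <- sens[sens$edh_index == "hc" & sens$response == "yield" &
                sens$window_end_year == 2018, ]
  row <- reg[reg$edh_index == "hc" & reg$response == "yield" &
               reg$window_end_year == 2018, ]
  expect_equal(row$median_r, median(one$r, na.rm = TRUE))
  expect_equal(row$frac_positive, mean(one$r > 0, na.rm = TRUE))
  # degenerate direction cases
  allpos <- dplyr::mutate(one, r = abs(r) + 0.01)
  expect_equal(regional_summary(allpos)$frac_positive, 1)
  sym <- dplyr::mutate(one, r = rep(c(-0.4, 0.4), length.out = nrow(one)))
  expect_equal(regional_summary(sym)$median_r, 0)
})
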