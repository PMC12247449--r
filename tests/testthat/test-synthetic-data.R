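test_that("configuration validation enforces the documented invariants", {
  expect_error(synthetic_config(years = c(2000, 2018)),
               class = "edhwheat_config_error") # 19 years < 21
  expect_error(synthetic_config(n_lat = 0), class = "edhwheat_config_error")
  expect_error(tiny_config(precip_dry_prob = 1.4),
               class = "edhwheat_config_error")
  expect_error(tiny_config(noise_sd_climate = -1),
               class = "edhwheat_config_error")
  expect_error(tiny_config(seasonal_temp_amplitude = -2),
               class = "edhwheat_config_error")
  expect_s3_class(tiny_config(), "edh_config")
})

test_that("degenerate deterministic configuration is exactly flat", {
  cfg <- tiny_config(noise_sd_climate = 0, annual_anomaly_sd = 0,
                     temp_trend = 0, seasonal_temp_amplitude = 0,
                     lat_temp_gradient = 0, base_tmax = 20,
                     diurnal_range_sd = 0)
  clim <- generate_daily_climate(cfg)
  expect_true(all(clim$tmax == 20))
  expect_true(all(clim$tmin == 10)) # tmax minus the fixed diurnal range
})

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- tiny_config()
  c1 <- generate_daily_climate(cfg)
  c2 <- generate_daily_climate(cfg)
  expect_identical(c1, c2)
  e1 <- compute_edh_field(c1)
  s1 <- generate_scenario_suite(e1, cfg)
  s2 <- generate_scenario_suite(e1, cfg)
  expect_identical(s1, s2)
  # a different variant redraws the weather, same structure
  c3 <- generate_daily_climate(cfg, variant = 2L)
  expect_false(identical(c1$tmax, c3$tmax))
  expect_identical(c1[c("cell", "lat", "lon", "date")],
                   c3[c("cell", "lat", "lon", "date")])
})

test_that("injected warming trend is recovered as an exact annual-mean slope", {
  cfg <- synthetic_config(n_lat = 1, n_lon = 1, years = c(1959, 2018),
                          temp_trend = 0.5, noise_sd_climate = 0,
                          annual_anomaly_sd = 0, diurnal_range_sd = 0)
  clim <- generate_daily_climate(cfg)
  annual <- clim |>
    dplyr::group_by(year = as.integer(format(date, "%Y"))) |>
    dplyr::summarise(tmax = mean(tmax))
  slope <- coef(lm(tmax ~ year, annual))[["year"]]
  expect_equal(slope, 0.05, tolerance = 1e-9)
})

test_that("generated climate and responses respect physical bounds", {
  cfg <- tiny_config()
  clim <- generate_daily_climate(cfg)
  expect_true(all(clim$tmax >= clim$tmin))
  expect_true(all(clim$precip >= 0))
  expect_true(!is.unsorted(clim$date[clim$cell == 1]))
  expect_true(all(diff(clim$date[clim$cell == 1]) == 1))
  edh <- compute_edh_field(clim)
  suite <- generate_scenario_suite(edh, cfg)
  expect_true(all(suite$yield >= 0))
  expect_setequal(unique(suite$scenario), scenario_labels())
})

test_that("unknown scenario labels and mismatched grids error", {
  cfg <- tiny_config()
  edh <- compute_edh_field(generate_daily_climate(cfg))
  expect_error(generate_scenario_outputs(edh, cfg, "S14"),
               class = "edhwheat_input_error")
  expect_error(generate_scenario_outputs(edh[edh$cell != 1, ], cfg, "S2"),
               class = "edhwheat_input_error")
})

test_that("zero-noise responses recover the injected betas by regression", {
  cfg <- tiny_config(noise_sd_response = zero_noise)
  edh <- compute_edh_field(generate_daily_climate(cfg))
  s2 <- generate_scenario_outputs(edh, cfg, "S2")
  x <- dplyr::inner_join(as.data.frame(edh), as.data.frame(s2),
                         by = c("cell", "lat", "lon", "year"))
  u <- x$year - min(x$year)
  fit_y <- lm(yield ~ u + hc + dc + cdhc, data = cbind(x, u = u))
  expect_equal(unname(coef(fit_y)[c("hc", "dc", "cdhc")]),
               unname(-cfg$beta_yield[c("hc", "dc", "cdhc")]),
               tolerance = 1e-8)
  fit_c <- lm(fco2 ~ u + hc + dc + cdhc, data = cbind(x, u = u))
  expect_equal(unname(coef(fit_c)[c("hc", "dc", "cdhc")]),
               unname(cfg$beta_fco2[c("hc", "dc", "cdhc")]),
               tolerance = 1e-8)
  fit_n <- lm(fn2o ~ u + hc + dc + cdhc, data = cbind(x, u = u))
  expect_equal(unname(coef(fit_n)[c("hc", "dc", "cdhc")]),
               unname(cfg$beta_fn2o[c("hc", "dc", "cdhc")]),
               tolerance = 1e-8)
  # ground-truth sidecar records the same coefficients
  gt <- attr(s2, "ground_truth")
  expect_equal(gt$betas$value[gt$betas$component == "beta_fco2"],
               unname(cfg$beta_fco2))
})

test_that("scenario construction is additive with exact single-driver recovery", {
  cfg <- tiny_config(noise_sd_response = zero_noise)
  edh <- compute_edh_field(generate_daily_climate(cfg))
  suite <- generate_scenario_suite(edh, cfg)
  pick <- function(s) suite[suite$scenario == s, ]

  # S1: all drivers constant, zero interannual variance per cell
  s1_var <- pick("S1") |>
    dplyr::group_by(cell) |>
    dplyr::summarise(v = var(yield) + var(fco2) + var(fn2o) + var(fch4))
  expect_true(all(s1_var$v == 0))

  # S2 - S7 isolates the fertiliser ramps exactly
  s2 <- pick("S2"); s7 <- pick("S7")
  u <- s2$year - min(s2$year)
  slopes <- cfg$driver_slopes
  nfer_yield <- sum(slopes$slope[slopes$driver == "nfer" &
                                   slopes$variable == "yield"])
  nfer_n2o <- sum(slopes$slope[slopes$driver == "nfer" &
                                 slopes$variable == "fn2o"])
  expect_equal(s2$yield - s7$yield, nfer_yield * u, tolerance = 1e-10)
  expect_equal(s2$fn2o - s7$fn2o, nfer_n2o * u, tolerance = 1e-10)

  # S3 removes exactly the climate coupling: S2 - S3 equals beta * EDH
  s3 <- pick("S3")
  e <- dplyr::arrange(as.data.frame(edh), cell, year)
  coupl <- cfg$beta_fco2[["hc"]] * e$hc + cfg$beta_fco2[["dc"]] * e$dc +
    cfg$beta_fco2[["cdhc"]] * e$cdhc
  expect_equal(s2$fco2 - s3$fco2, coupl, tolerance = 1e-10)

  # NT/CT multipliers touch only the CO2 flux, inside the configured regions
  s12 <- pick("S12")
  expect_equal(s12$yield, s2$yield)
  expect_equal(s12$fn2o, s2$fn2o)
  mult <- edhwheat:::tillage_multiplier(cfg, "S12")
  expect_equal(s12$fco2 - s2$fco2, (mult[s2$cell] - 1) * coupl,
               tolerance = 1e-10)
})

test_that("perfect linear coupling yields unit-magnitude correlation", {
  # single index active, no noise, no other yield variation:
  # Pearson R(HC, yield) = -1 exactly
  flat_slopes <- dplyr::mutate(default_driver_slopes(), slope = 0)
  cfg <- tiny_config(
    noise_sd_response = zero_noise,
    beta_yield = c(hc = 8, dc = 0, cdhc = 0),
    beta_fco2 = c(hc = 0, dc = 0, cdhc = 0),
    driver_slopes = flat_slopes,
    drying_trend = 0, temp_trend = 0
  )
  edh <- compute_edh_field(generate_daily_climate(cfg))
  s2 <- generate_scenario_outputs(edh, cfg, "S2")
  x <- dplyr::inner_join(as.data.frame(edh), as.data.frame(s2),
                         by = c("cell", "lat", "lon", "year"))
  rs <- x |>
    dplyr::group_by(cell) |>
    dplyr::summarise(r = cor(hc, yield))
  expect_equal(rs$r, rep(-1, nrow(rs)), tolerance = 1e-12)
})
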