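#' CO2-equivalent conversion of gas fluxes
#'
#' Linear, unit-agnostic converters from elemental-mass fluxes to CO2
#' equivalents on the 100-year global warming potential scale:
#' \deqn{E_{CO_2} = F_{CO_2} \cdot 44/12,\quad
#'       E_{N_2O} = F_{N_2O} \cdot 44/28 \cdot 273,\quad
#'       E_{CH_4} = F_{CH_4} \cdot 16/12 \cdot 27,}
#' i.e. molar mass conversion from g C (or g N) to gas mass, times the
#' GWP100 factor (N2O 273, CH4 27; CO2 1). The caller declares the mass
#' unit; whatever unit the flux carries, the result is the same unit of
#' CO2 equivalents. Negative CO2 flux denotes net soil-carbon
#' sequestration and converts to a negative (sink) equivalent.
#'
#' @param fco2 CO2 flux as carbon mass (e.g. g C m\eqn{^{-2}} yr\eqn{^{-1}}
#'   or Tg C yr\eqn{^{-1}}).
#' @param fn2o N2O flux as nitrogen mass.
#' @param fch4 CH4 flux as carbon mass.
#' @return CO2-equivalent mass in the input's mass unit.
#' @examples
#' co2_to_co2eq(12) # 44
#' n2o_to_co2eq(28) # 12012
#' ch4_to_co2eq(12) # 432
#' @export
co2_to_co2eq <- function(fco2) fco2 / 12 * 44

#' @rdname co2_to_co2eq
#' @export
n2o_to_co2eq <- function(fn2o) fn2o / 28 * 44 * 273

#' @rdname co2_to_co2eq
#' @export
ch4_to_co2eq <- function(fch4) fch4 / 12 * 16 * 27

#' Net greenhouse-gas balance
#'
#' Sum of the three CO2-equivalent components,
#' \eqn{E_{GHG} = E_{CO_2} + E_{N_2O} + E_{CH_4}}.
#'
#' @param eco2,en2o,ech4 CO2-equivalent fluxes in a common unit.
#' @return Net CO2-equivalent flux.
#' @export
net_ghg <- function(eco2, en2o, ech4) eco2 + en2o + ech4

#' Greenhouse-gas emission intensity
#'
#' \eqn{GHGI = E_{GHG} / Y}: net CO2-equivalent emissions per unit of
#' production. Yields at or below `y_min` (near-failure years) are masked
#' to `NA` rather than producing unbounded ratios; masked values propagate
#' as missing through the sensitivity analysis.
#'
#' @param eghg Net CO2-equivalent emissions (e.g. kg CO2-eq/ha).
#' @param y Production or yield, non-negative (e.g. kg/ha).
#' @param y_min Mask threshold on `y`, same unit as `y`.
#' @return Intensity (e.g. kg CO2-eq per kg), `NA` where masked.
#' @examples
#' ghgi(100, 50)
#' ghgi(100, 0) # masked
#' @export
ghgi <- function(eghg, y, y_min = 1) {
  if (any(y < 0, na.rm = TRUE)) stop_input("`y` must be non-negative.")
  ifelse(!is.na(y) & y > y_min, eghg / y, NA_real_)
}

#' Per-cell annual GHG balance and intensity of a scenario field
#'
#' Converts the per-area gas fluxes of a scenario table (g C or g N
#' m\eqn{^{-2}} yr\eqn{^{-1}}) to kg CO2-eq ha\eqn{^{-1}} yr\eqn{^{-1}}
#' (factor 10 for g m\eqn{^{-2}} to kg ha\eqn{^{-1}} on top of the GWP100
#' conversion), sums them to the net balance and divides by yield for the
#' intensity.
#'
#' @param scenario An `edh_scenario` tibble (one or more scenarios).
#' @param y_min Yield mask threshold for the intensity, kg/ha.
#' @return The input plus columns `eco2`, `en2o`, `ech4`, `eghg`
#'   (kg CO2-eq/ha) and `ghgi` (kg CO2-eq per kg grain).
#' @examples
#' cfg <- synthetic_config(n_lat = 2, n_lon = 2, years = c(1998, 2018))
#' edh <- compute_edh_field(generate_daily_climate(cfg))
#' ghg_intensity(generate_scenario_outputs(edh, cfg, "S2"))
#' @export
ghg_intensity <- function(scenario, y_min = 1) {
  check_columns(scenario, c("cell", "year", "yield", "fco2", "fn2o", "fch4"),
                "scenario")
  g_m2_to_kg_ha <- 10
  out <- scenario |>
    dplyr::mutate(
      eco2 = co2_to_co2eq(.data$fco2) * g_m2_to_kg_ha,
      en2o = n2o_to_co2eq(.data$fn2o) * g_m2_to_kg_ha,
      ech4 = ch4_to_co2eq(.data$fch4) * g_m2_to_kg_ha,
      eghg = net_ghg(.data$eco2, .data$en2o, .data$ech4),
      ghgi = ghgi(.data$eghg, .data$yield, y_min = y_min)
    )
  as_edh_tbl(out, "edh_scenario")
}

check_matching_grids <- function(a, b, what_a, what_b) {
  oa <- order(a$cell, a$year)
  ob <- order(b$cell, b$year)
  if (nrow(a) != nrow(b) ||
      !all(a$cell[oa] == b$cell[ob]) || !all(a$year[oa] == b$year[ob])) {
    stop_input("`%s` and `%s` are on mismatched grids/years.", what_a, what_b)
  }
  invisible(NULL)
}

#' Factorial attribution of one driver
#'
#' Contribution of a single driver as the elementwise difference between the
#' all-drivers run and the run with that driver held constant
#' (`s2 - s_without`), for each response variable. With `s_without = S1`
#' (all drivers constant) the result is the all-factor net effect. The
#' companion [attribute_lulc()] uses the S10 − S11 pair, which isolates
#' land-use change while management is held at its earliest level in both
#' runs.
#'
#' @param s2 `edh_scenario` tibble of the all-drivers run.
#' @param s_without `edh_scenario` tibble of the all-drivers-without-one
#'   run, on the same grid, years and wheat type.
#' @param factor Label for the driver being isolated (e.g. `"climate"`,
#'   `"nfer"`, `"tillage"`).
#' @param variables Response columns to difference.
#' @return A tibble of class `edh_attribution`: `cell`, `lat`, `lon`,
#'   `year`, `factor`, `variable`, `contribution` (same unit as the
#'   response).
#' @examples
#' cfg <- synthetic_config(n_lat = 2, n_lon = 2, years = c(1998, 2018),
#'                         noise_sd_response = c(yield = 0, fco2 = 0,
#'                                               fn2o = 0, fch4 = 0))
#' edh <- compute_edh_field(generate_daily_climate(cfg))
#' s2 <- generate_scenario_outputs(edh, cfg, "S2")
#' s3 <- generate_scenario_outputs(edh, cfg, "S3")
#' attribute_factor(s2, s3, "climate")
#' @export
attribute_factor <- function(s2, s_without, factor,
                             variables = c("yield", "fco2", "fn2o", "fch4")) {
  check_columns(s2, c("cell", "lat", "lon", "year", variables), "s2")
  check_columns(s_without, c("cell", "year", variables), "s_without")
  a <- dplyr::arrange(s2, .data$cell, .data$year)
  b <- dplyr::arrange(s_without, .data$cell, .data$year)
  check_matching_grids(a, b, "s2", "s_without")
  if ("wheat_type" %in% names(a) && "wheat_type" %in% names(b) &&
      !identical(unique(a$wheat_type), unique(b$wheat_type))) {
    stop_input("`s2` and `s_without` are for different wheat types.")
  }
  out <- purrr::map_dfr(variables, function(v) {
    tibble::tibble(
      cell = a$cell, lat = a$lat, lon = a$lon, year = a$year,
      factor = factor, variable = v,
      contribution = a[[v]] - b[[v]]
    )
  })
  as_edh_tbl(out, "edh_attribution")
}

#' @rdname attribute_factor
#' @param s10,s11 Scenario runs with management fixed at its earliest level,
#'   differing only in whether land cover varies.
#' @export
attribute_lulc <- function(s10, s11,
                           variables = c("yield", "fco2", "fn2o", "fch4")) {
  attribute_factor(s10, s11, factor = "lulc_managed_constant",
                   variables = variables)
}

#' Attribute every driver of a scenario suite
#'
#' Convenience wrapper running [attribute_factor()] for the seven
#' single-driver pairs (S2 minus each of S3–S9) and the all-factor pair
#' (S2 − S1) of a bound scenario suite.
#'
#' @param suite `edh_scenario` tibble holding at least scenarios S1–S9, as
#'   from [generate_scenario_suite()].
#' @inheritParams attribute_factor
#' @return `edh_attribution` tibble with factors `climate`, `co2`, `ndep`,
#'   `lulc`, `nfer`, `irrigation`, `tillage` and `all`.
#' @export
attribute_all <- function(suite, variables = c("yield", "fco2", "fn2o", "fch4")) {
  check_columns(suite, c("scenario"), "suite")
  pick <- function(s) dplyr::filter(suite, .data$scenario == s)
  s2 <- pick("S2")
  pairs <- c(climate = "S3", co2 = "S4", ndep = "S5", lulc = "S6",
             nfer = "S7", irrigation = "S8", tillage = "S9", all = "S1")
  out <- purrr::imap_dfr(pairs, function(s, f) {
    attribute_factor(s2, pick(s), factor = f, variables = variables)
  })
  as_edh_tbl(out, "edh_attribution")
}

#' Area-weighted regional totals of attributed contributions
#'
#' Aggregates per-cell contributions with spherical cell-area weights times
#' a wheat area fraction (defaulting to 1 on synthetic grids).
#'
#' @param attribution `edh_attribution` tibble.
#' @param wheat_fraction Optional tibble (`cell`, `fraction`) of the cell
#'   fraction actually under wheat.
#' @return Tibble with `factor`, `variable`, `year`,
#'   `total` (contribution × km\eqn{^2}-weighted area sum) and
#'   `area_weighted_mean`.
#' @export
attribution_totals <- function(attribution, wheat_fraction = NULL) {
  check_columns(attribution, c("cell", "lat", "lon", "year", "factor",
                               "variable", "contribution"), "attribution")
  lats <- sort(unique(attribution$lat))
  lons <- sort(unique(attribution$lon))
  dlat <- if (length(lats) > 1) min(diff(lats)) else 1
  dlon <- if (length(lons) > 1) min(diff(lons)) else 1
  x <- attribution |>
    dplyr::mutate(area = cell_area_km2(.data$lat, dlat, dlon))
  if (!is.null(wheat_fraction)) {
    check_columns(wheat_fraction, c("cell", "fraction"), "wheat_fraction")
    x <- dplyr::left_join(x, wheat_fraction, by = "cell") |>
      dplyr::mutate(area = .data$area * dplyr::coalesce(.data$fraction, 1))
  }
  x |>
    dplyr::group_by(.data$factor, .data$variable, .data$year) |>
    dplyr::summarise(
      total = sum(.data$contribution * .data$area),
      area_weighted_mean = sum(.data$contribution * .data$area) / sum(.data$area),
      .groups = "drop"
    )
}

#' Model-evaluation metrics
#'
#' Coefficient of determination of the ordinary least squares regression of
#' simulations on observations, root mean square error
#' \eqn{\sqrt{\mathrm{mean}((sim-obs)^2)}}, and the normalised RMSE
#' (RMSE divided by the observation mean).
#'
#' @param obs,sim Equal-length numeric vectors, `n >= 3`.
#' @return A one-row tibble of class `edh_fit`: `r2`, `rmse`, `nrmse`, `n`.
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 6))
#' @export
fit_metrics <- function(obs, sim) {
  if (length(obs) != length(sim)) stop_input("`obs` and `sim` differ in length.")
  ok <- stats::complete.cases(obs, sim)
  obs <- obs[ok]; sim <- sim[ok]
  if (length(obs) < 3) stop_input("Need at least 3 paired values.")
  if (stats::sd(obs) == 0) {
    stop_input("`obs` has zero variance; R^2 is undefined.")
  }
  rmse <- sqrt(mean((sim - obs)^2))
  if (abs(mean(obs)) < .Machine$double.eps) {
    stop_input("`mean(obs)` is zero; nRMSE is undefined.")
  }
  out <- tibble::tibble(
    r2 = if (stats::sd(sim) == 0) 0 else stats::cor(obs, sim)^2,
    rmse = rmse,
    nrmse = rmse / mean(obs),
    n = length(obs)
  )
  as_edh_tbl(out, "edh_fit")
}
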