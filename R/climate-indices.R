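#' Extraterrestrial solar radiation
#'
#' Daily extraterrestrial radiation at the top of the atmosphere,
#' \deqn{R_a = \frac{S_0}{\pi}\left(\frac{r_0}{r}\right)^2
#'   \left[H \sin\phi \sin\delta + \sin H \cos\phi \cos\delta\right],}
#' with the solar constant \eqn{S_0 = 118.02} MJ m\eqn{^{-2}} d\eqn{^{-1}},
#' solar declination \eqn{\delta}, inverse relative Earth–Sun distance squared
#' \eqn{(r_0/r)^2} and sunset hour angle \eqn{H} from the standard FAO-56
#' approximations:
#' \eqn{\delta = 0.409\sin(2\pi J/365 - 1.39)},
#' \eqn{(r_0/r)^2 = 1 + 0.033\cos(2\pi J/365)},
#' \eqn{H = \arccos(\mathrm{clamp}(-\tan\phi\tan\delta, -1, 1))}.
#' Polar night (argument of arccos above 1) gives \eqn{H = 0} and hence
#' \eqn{R_a = 0}.
#'
#' @param latitude Latitude in decimal degrees, in \eqn{[-90, 90]}. Recycled
#'   against `day_of_year`.
#' @param day_of_year Integer day of year, 1–366.
#' @return Radiation in MJ m\eqn{^{-2}} d\eqn{^{-1}}, never negative.
#' @examples
#' extraterrestrial_radiation(40, 196)
#' extraterrestrial_radiation(80, 1) # polar night, 0
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    stop_input("`latitude` must lie in [-90, 90] degrees.")
  }
  if (any(day_of_year < 1 | day_of_year > 366, na.rm = TRUE)) {
    stop_input("`day_of_year` must lie in [1, 366].")
  }
  phi <- latitude * pi / 180
  j <- day_of_year
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  dr2 <- 1 + 0.033 * cos(2 * pi * j / 365)
  ra_from_geometry(phi, delta, dr2)
}

# Eq.-9 kernel on raw solar geometry (phi, delta in radians); separated so the
# geometry inputs can be probed directly.
ra_from_geometry <- function(phi, delta, dr2) {
  s0 <- 118.02
  hs <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  ra <- s0 / pi * dr2 * (hs * sin(phi) * sin(delta) + sin(hs) * cos(phi) * cos(delta))
  pmax(ra, 0)
}

#' Hargreaves potential evapotranspiration
#'
#' Temperature-and-radiation estimator of daily potential evapotranspiration,
#' \deqn{ET_p = 0.0023 \times 0.408 R_a (T_{max} - T_{min})^{0.5} (T + 17.8),}
#' where \eqn{T = (T_{max} + T_{min})/2} and the factor 0.408 converts
#' MJ m\eqn{^{-2}} d\eqn{^{-1}} to mm d\eqn{^{-1}} of water equivalent.
#' The result is floored at zero (it can only go negative for mean
#' temperatures below \eqn{-17.8}°C, where evaporative demand is nil).
#'
#' @param tmax,tmin Daily maximum / minimum air temperature, °C. `tmax` must
#'   be at least `tmin` elementwise.
#' @param ra Extraterrestrial radiation, MJ m\eqn{^{-2}} d\eqn{^{-1}}, as from
#'   [extraterrestrial_radiation()].
#' @return Potential evapotranspiration, mm d\eqn{^{-1}}.
#' @examples
#' hargreaves_etp(30, 20, 37.566)
#' @export
hargreaves_etp <- function(tmax, tmin, ra) {
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop_input("`tmax` must be >= `tmin` at every element.")
  }
  if (any(ra < 0, na.rm = TRUE)) stop_input("`ra` must be non-negative.")
  tmean <- (tmax + tmin) / 2
  pmax(0.0023 * 0.408 * ra * sqrt(tmax - tmin) * (tmean + 17.8), 0)
}

#' Daily aridity index
#'
#' Ratio of daily precipitation to potential evapotranspiration,
#' \eqn{AI = P / ET_p}. Days with \eqn{ET_p} at or below `etp_min` have an
#' undefined index and return `NA`; such days never count as dry
#' (frozen or polar days are not meteorological drought in this framework).
#'
#' @param p Daily precipitation, mm d\eqn{^{-1}}, non-negative.
#' @param etp Daily potential evapotranspiration, mm d\eqn{^{-1}},
#'   non-negative.
#' @param etp_min Division guard below which AI is undefined (mm
#'   d\eqn{^{-1}}).
#' @return Dimensionless index, `NA` where undefined.
#' @examples
#' aridity_index(c(0, 1, 3), c(5, 5, 0))
#' @export
aridity_index <- function(p, etp, etp_min = 1e-6) {
  if (any(p < 0, na.rm = TRUE)) stop_input("`p` must be non-negative.")
  if (any(etp < 0, na.rm = TRUE)) stop_input("`etp` must be non-negative.")
  out <- ifelse(etp > etp_min, p / etp, NA_real_)
  out
}

# Shared window bookkeeping: Mar 1 - Sep 30 of `year`, 214 days always
# (February is outside the window, so leap years change nothing).
edh_window_days <- function() 214L

check_window_series <- function(dates, year, what) {
  lt <- as.POSIXlt(dates)
  keep <- (lt$year + 1900L) == year & (lt$mon + 1L) %in% 3:9
  d <- dates[keep]
  if (length(d) != edh_window_days() || any(diff(as.integer(d)) != 1L)) {
    stop_input(
      "`%s` must cover Mar 1-Sep 30 of %d without gaps (%d daily values); got %d.",
      what, year, edh_window_days(), length(d)
    )
  }
  keep
}

#' Annual extreme-day counts for one daily series
#'
#' Count, over the fixed Mar 1–Sep 30 growing window of one calendar year,
#' the heat days (`count_heat_days`: daily maximum temperature strictly above
#' `heat_threshold`), the dry days (`count_dry_days`: aridity index strictly
#' below `aridity_threshold`, undefined days excluded), and the compound
#' dry-heat days (`count_compound_days`: both conditions on the same day; no
#' cascading or lag logic). The window always holds 214 days; series with
#' gaps raise an error rather than being imputed.
#'
#' @param dates Daily `Date` vector covering at least Mar 1–Sep 30 of `year`.
#' @param tmax Daily maximum temperature, °C, aligned with `dates`.
#' @param ai Daily aridity index, as from [aridity_index()]; `NA` marks
#'   undefined days.
#' @param year Calendar year to count within.
#' @param heat_threshold Heat-day temperature threshold, °C.
#' @param aridity_threshold Dry-day aridity threshold (dimensionless).
#' @return Integer day count in \eqn{[0, 214]}.
#' @examples
#' d <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
#' count_heat_days(d, rep(35, length(d)), 2000)
#' @export
count_heat_days <- function(dates, tmax, year, heat_threshold = 30) {
  stopifnot(length(dates) == length(tmax))
  keep <- check_window_series(dates, year, "dates")
  sum(tmax[keep] > heat_threshold)
}

#' @rdname count_heat_days
#' @export
count_dry_days <- function(dates, ai, year, aridity_threshold = 0.2) {
  stopifnot(length(dates) == length(ai))
  keep <- check_window_series(dates, year, "dates")
  sum(ai[keep] < aridity_threshold, na.rm = TRUE)
}

#' @rdname count_heat_days
#' @export
count_compound_days <- function(dates, tmax, ai, year, heat_threshold = 30,
                                aridity_threshold = 0.2) {
  stopifnot(length(dates) == length(tmax), length(dates) == length(ai))
  keep <- check_window_series(dates, year, "dates")
  sum(tmax[keep] > heat_threshold & ai[keep] < aridity_threshold, na.rm = TRUE)
}

#' Annual heat, dry and compound dry-heat day counts on a grid
#'
#' Apply the daily water balance (extraterrestrial radiation, Hargreaves
#' potential evapotranspiration, aridity index) and the three extreme-day
#' counters to every cell and year of a daily climate table. Counting is
#' restricted to the Mar 1–Sep 30 window (214 days; February is excluded so
#' leap years do not change the window length). Every cell-year must cover
#' the window completely; gaps raise an error.
#'
#' @param climate Daily climate tibble with columns `cell`, `lat`, `lon`,
#'   `date`, `tmax`, `tmin`, `precip`, as from [generate_daily_climate()] or
#'   [read_climate_nc()].
#' @param heat_threshold Heat-day threshold on daily maximum temperature, °C.
#' @param aridity_threshold Dry-day threshold on the daily aridity index.
#' @return A tibble of class `edh_field` with one row per cell and year:
#'   columns `cell`, `lat`, `lon`, `year`, `hc`, `dc`, `cdhc`, `n_days`.
#' @examples
#' cfg <- synthetic_config(n_lat = 2, n_lon = 2, years = c(1995, 2016))
#' clim <- generate_daily_climate(cfg)
#' compute_edh_field(clim)
#' @export
compute_edh_field <- function(climate, heat_threshold = 30,
                              aridity_threshold = 0.2) {
  check_columns(climate, c("cell", "lat", "lon", "date", "tmax", "tmin", "precip"),
                "climate")
  if (any(climate$tmax < climate$tmin)) {
    stop_input("`climate` violates tmax >= tmin.")
  }
  lt <- as.POSIXlt(climate$date)
  doy <- lt$yday + 1L
  month <- lt$mon + 1L
  year <- lt$year + 1900L

  in_window <- month %in% 3:9
  x <- climate[in_window, c("cell", "lat", "lon", "tmax", "tmin", "precip")]
  x$year <- year[in_window]
  ra <- extraterrestrial_radiation(x$lat, doy[in_window])
  etp <- hargreaves_etp(x$tmax, x$tmin, ra)
  ai <- aridity_index(x$precip, etp)
  hot <- x$tmax > heat_threshold
  dry <- !is.na(ai) & ai < aridity_threshold

  out <- x |>
    dplyr::mutate(.hot = hot, .dry = dry) |>
    dplyr::group_by(.data$cell, .data$lat, .data$lon, .data$year) |>
    dplyr::summarise(
      hc = sum(.data$.hot),
      dc = sum(.data$.dry),
      cdhc = sum(.data$.hot & .data$.dry),
      n_days = dplyr::n(),
      .groups = "drop"
    )
  bad <- out$n_days != edh_window_days()
  if (any(bad)) {
    stop_input(
      "Incomplete Mar 1-Sep 30 coverage for %d cell-year(s) (expected %d days).",
      sum(bad), edh_window_days()
    )
  }
  as_edh_tbl(out, "edh_field")
}
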