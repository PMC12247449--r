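# NetCDF (CF-style dims lon/lat/time|year) and long-format CSV readers and
# writers for the gridded types. Values are stored as float32 on disk;
# computation stays float64 in memory, so round-trips are exact to float32
# precision. Every writer records the thresholds/provenance attributes it was
# given; none writes timestamps, so identical data produce identical bytes.

require_regular_grid <- function(x, what) {
  lats <- sort(unique(x$lat))
  lons <- sort(unique(x$lon))
  grid <- tidyr::expand_grid(lat = lats, lon = lons)
  cells <- dplyr::distinct(x, .data$lat, .data$lon)
  if (nrow(cells) != nrow(grid) ||
      nrow(dplyr::anti_join(grid, cells, by = c("lat", "lon"))) > 0) {
    stop_schema("`%s` does not cover a full regular lat/lon grid.", what)
  }
  list(lats = lats, lons = lons)
}

nc_global_attrs <- function(nc, attrs) {
  for (nm in names(attrs)) {
    if (!is.null(attrs[[nm]])) {
      ncdf4::ncatt_put(nc, 0, nm, attrs[[nm]])
    }
  }
}

nc_check_vars <- function(nc, path, required) {
  have <- names(nc$var)
  missing <- setdiff(required, have)
  if (length(missing)) {
    ncdf4::nc_close(nc)
    stop_schema("NetCDF file '%s' is missing variable(s): %s (required: %s).",
                path, paste(missing, collapse = ", "),
                paste(required, collapse = ", "))
  }
}

nc_check_units <- function(nc, path, units) {
  for (v in names(units)) {
    got <- ncdf4::ncatt_get(nc, v, "units")
    if (got$hasatt && !identical(got$value, units[[v]])) {
      ncdf4::nc_close(nc)
      stop_schema(
        "NetCDF file '%s': variable '%s' has units '%s', expected '%s' (no silent conversion).",
        path, v, got$value, units[[v]]
      )
    }
  }
}

# cell id convention used on disk and by config_grid(): row-major over
# (lat_idx, lon_idx), i.e. cell = (lat_idx - 1) * n_lon + lon_idx.
grid_cell_id <- function(lat, lon, lats, lons) {
  (match(lat, lats) - 1L) * length(lons) + match(lon, lons)
}

# Reshape a long value vector to the [lon, lat, time] array ncdf4 expects.
to_nc_array <- function(x, value, lats, lons, time_col) {
  times <- sort(unique(x[[time_col]]))
  arr <- array(NA_real_, dim = c(length(lons), length(lats), length(times)))
  arr[cbind(match(x$lon, lons), match(x$lat, lats),
            match(x[[time_col]], times))] <- x[[value]]
  list(arr = arr, times = times)
}

.climate_units <- c(tmax = "degC", tmin = "degC", precip = "mm d-1")

#' Read and write daily climate grids as CF-style NetCDF
#'
#' `write_climate_nc()` stores a daily climate tibble with dimensions
#' `lon`, `lat`, `time` (days since 1900-01-01) and float32 variables
#' `tmax`, `tmin` (degC) and `precip` (mm d-1). `read_climate_nc()`
#' restores the tibble, validating that all required variables and
#' dimensions exist (a schema error names the offender) and that declared
#' units match — unit mismatches error rather than silently converting.
#'
#' @param climate `edh_climate` tibble (full regular grid).
#' @param path File path.
#' @param attrs Named list of extra global attributes (provenance: seed,
#'   configuration hash, stage versions, ...).
#' @return `read_climate_nc()` returns an `edh_climate` tibble;
#'   `write_climate_nc()` returns `path` invisibly.
#' @export
write_climate_nc <- function(climate, path, attrs = list()) {
  check_columns(climate, c("cell", "lat", "lon", "date", "tmax", "tmin",
                           "precip"), "climate")
  g <- require_regular_grid(climate, "climate")
  origin <- as.Date("1900-01-01")
  x <- dplyr::mutate(climate, time = as.integer(.data$date - origin))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  dim_time <- ncdf4::ncdim_def("time", "days since 1900-01-01",
                               sort(unique(x$time)), unlim = FALSE)
  vars <- lapply(names(.climate_units), function(v) {
    ncdf4::ncvar_def(v, .climate_units[[v]], list(dim_lon, dim_lat, dim_time),
                     missval = 1e30, prec = "float")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (v in names(.climate_units)) {
    ncdf4::ncvar_put(nc, v, to_nc_array(x, v, g$lats, g$lons, "time")$arr)
  }
  nc_global_attrs(nc, c(list(package = "edhwheat"), attrs))
  invisible(path)
}

#' @rdname write_climate_nc
#' @export
read_climate_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  nc_check_vars(nc, path, c("tmax", "tmin", "precip"))
  nc_check_units(nc, path, as.list(.climate_units))
  lons <- nc$dim$lon$vals
  lats <- nc$dim$lat$vals
  times <- nc$dim$time$vals
  dates <- as.Date("1900-01-01") + times
  get <- function(v) as.vector(ncdf4::ncvar_get(nc, v))
  out <- tidyr::expand_grid(date = dates, lat = lats, lon = lons) |>
    dplyr::arrange(.data$date, .data$lat, .data$lon)
  # expand_grid above runs lon fastest, matching the nc array layout
  out$tmax <- get("tmax")
  out$tmin <- get("tmin")
  out$precip <- get("precip")
  ncdf4::nc_close(nc)
  out <- out |>
    dplyr::mutate(cell = grid_cell_id(.data$lat, .data$lon, lats, lons)) |>
    dplyr::arrange(.data$cell, .data$date) |>
    dplyr::select("cell", "lat", "lon", "date", "tmax", "tmin", "precip")
  as_edh_tbl(out, "edh_climate")
}

.edh_units <- c(hc = "days", dc = "days", cdhc = "days", n_days = "days")

#' Read and write annual extreme-day fields as NetCDF
#'
#' Dimensions `lon`, `lat`, `year`; integer variables `hc`, `dc`, `cdhc`
#' and `n_days` (window length).
#'
#' @param edh `edh_field` tibble.
#' @inheritParams write_climate_nc
#' @return `read_edh_nc()` returns an `edh_field` tibble;
#'   `write_edh_nc()` returns `path` invisibly.
#' @export
write_edh_nc <- function(edh, path, attrs = list()) {
  check_columns(edh, c("cell", "lat", "lon", "year", "hc", "dc", "cdhc",
                       "n_days"), "edh")
  g <- require_regular_grid(edh, "edh")
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  dim_year <- ncdf4::ncdim_def("year", "calendar year", sort(unique(edh$year)))
  vars <- lapply(names(.edh_units), function(v) {
    ncdf4::ncvar_def(v, .edh_units[[v]], list(dim_lon, dim_lat, dim_year),
                     missval = -1L, prec = "integer")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (v in names(.edh_units)) {
    ncdf4::ncvar_put(nc, v, to_nc_array(edh, v, g$lats, g$lons, "year")$arr)
  }
  nc_global_attrs(nc, c(list(package = "edhwheat"), attrs))
  invisible(path)
}

#' @rdname write_edh_nc
#' @export
read_edh_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  nc_check_vars(nc, path, c("hc", "dc", "cdhc", "n_days"))
  lons <- nc$dim$lon$vals
  lats <- nc$dim$lat$vals
  years <- nc$dim$year$vals
  out <- tidyr::expand_grid(year = years, lat = lats, lon = lons) |>
    dplyr::arrange(.data$year, .data$lat, .data$lon)
  for (v in c("hc", "dc", "cdhc", "n_days")) {
    out[[v]] <- as.integer(ncdf4::ncvar_get(nc, v))
  }
  ncdf4::nc_close(nc)
  out <- out |>
    dplyr::mutate(cell = grid_cell_id(.data$lat, .data$lon, lats, lons)) |>
    dplyr::arrange(.data$cell, .data$year) |>
    dplyr::select("cell", "lat", "lon", "year", "hc", "dc", "cdhc", "n_days")
  as_edh_tbl(out, "edh_field")
}

.scenario_units <- c(yield = "kg ha-1", fco2 = "g C m-2 yr-1",
                     fn2o = "g N m-2 yr-1", fch4 = "g C m-2 yr-1")

#' Read and write annual scenario fields (NetCDF and long CSV)
#'
#' One scenario per NetCDF file: dimensions `lon`, `lat`, `year`, float32
#' variables `yield`, `fco2`, `fn2o`, `fch4` and global attributes
#' `scenario` and `wheat_type`. The CSV form is the tidy long format
#' (`cell`, `lat`, `lon`, `year`, `scenario`, `wheat_type`, `variable`,
#' `value`) and may hold several scenarios. When a ground-truth sidecar
#' attribute is present, `write_scenario_nc()` also writes
#' `<path>_ground_truth.csv` with the injected coefficients — analysis
#' code never reads that file.
#'
#' @param scenario `edh_scenario` tibble (single scenario for NetCDF).
#' @inheritParams write_climate_nc
#' @return Readers return `edh_scenario` tibbles; writers return `path`
#'   invisibly.
#' @export
write_scenario_nc <- function(scenario, path, attrs = list()) {
  check_columns(scenario, c("cell", "lat", "lon", "year", "scenario",
                            "wheat_type", names(.scenario_units)), "scenario")
  if (dplyr::n_distinct(scenario$scenario) != 1) {
    stop_input("`write_scenario_nc()` expects a single scenario per file.")
  }
  g <- require_regular_grid(scenario, "scenario")
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  dim_year <- ncdf4::ncdim_def("year", "calendar year",
                               sort(unique(scenario$year)))
  vars <- lapply(names(.scenario_units), function(v) {
    ncdf4::ncvar_def(v, .scenario_units[[v]], list(dim_lon, dim_lat, dim_year),
                     missval = 1e30, prec = "float")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (v in names(.scenario_units)) {
    ncdf4::ncvar_put(nc, v, to_nc_array(scenario, v, g$lats, g$lons, "year")$arr)
  }
  nc_global_attrs(nc, c(list(package = "edhwheat",
                             scenario = scenario$scenario[1],
                             wheat_type = scenario$wheat_type[1]), attrs))
  gt <- attr(scenario, "ground_truth")
  if (!is.null(gt) && !is.null(gt$betas)) {
    readr::write_csv(gt$betas, paste0(path, "_ground_truth.csv"))
  }
  invisible(path)
}

#' @rdname write_scenario_nc
#' @export
read_scenario_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  nc_check_vars(nc, path, names(.scenario_units))
  nc_check_units(nc, path, as.list(.scenario_units))
  lons <- nc$dim$lon$vals
  lats <- nc$dim$lat$vals
  years <- nc$dim$year$vals
  scen <- ncdf4::ncatt_get(nc, 0, "scenario")
  wt <- ncdf4::ncatt_get(nc, 0, "wheat_type")
  out <- tidyr::expand_grid(year = years, lat = lats, lon = lons) |>
    dplyr::arrange(.data$year, .data$lat, .data$lon)
  for (v in names(.scenario_units)) {
    out[[v]] <- as.vector(ncdf4::ncvar_get(nc, v))
  }
  ncdf4::nc_close(nc)
  out <- out |>
    dplyr::mutate(
      cell = grid_cell_id(.data$lat, .data$lon, lats, lons),
      scenario = if (scen$hasatt) scen$value else NA_character_,
      wheat_type = if (wt$hasatt) wt$value else NA_character_
    ) |>
    dplyr::arrange(.data$cell, .data$year) |>
    dplyr::select("cell", "lat", "lon", "year", "scenario", "wheat_type",
                  "yield", "fco2", "fn2o", "fch4")
  as_edh_tbl(out, "edh_scenario")
}

#' @rdname write_scenario_nc
#' @export
write_scenario_csv <- function(scenario, path) {
  check_columns(scenario, c("cell", "lat", "lon", "year", "scenario",
                            "wheat_type", names(.scenario_units)), "scenario")
  long <- scenario |>
    tidyr::pivot_longer(dplyr::all_of(names(.scenario_units)),
                        names_to = "variable", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_scenario_nc
#' @export
read_scenario_csv <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(long, c("cell", "lat", "lon", "year", "scenario",
                        "wheat_type", "variable", "value"), "scenario csv")
  bad <- setdiff(unique(long$variable), names(.scenario_units))
  if (length(bad)) {
    stop_schema("Unknown scenario variable(s) in '%s': %s.",
                path, paste(bad, collapse = ", "))
  }
  out <- long |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$cell, .data$year) |>
    dplyr::select("cell", "lat", "lon", "year", "scenario", "wheat_type",
                  "yield", "fco2", "fn2o", "fch4")
  as_edh_tbl(out, "edh_scenario")
}

#' Read and write sensitivity fields as NetCDF
#'
#' Dimensions `lon`, `lat`, `window_end_year`; one float32 variable
#' `r_<index>_<response>` per index-response pair; global attributes
#' `method`, `dataset_variant` and `window_length`.
#'
#' @param sens `edh_sensitivity` tibble (single method and variant).
#' @inheritParams write_climate_nc
#' @return `read_sensitivity_nc()` returns an `edh_sensitivity` tibble;
#'   the writer returns `path` invisibly.
#' @export
write_sensitivity_nc <- function(sens, path, attrs = list()) {
  check_columns(sens, c("cell", "lat", "lon", "window_end_year", "edh_index",
                        "response", "method", "dataset_variant", "r"), "sens")
  if (dplyr::n_distinct(sens$method) != 1 ||
      dplyr::n_distinct(sens$dataset_variant) != 1) {
    stop_input("`write_sensitivity_nc()` expects one method x variant per file.")
  }
  g <- require_regular_grid(sens, "sens")
  years <- sort(unique(sens$window_end_year))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  dim_year <- ncdf4::ncdim_def("window_end_year", "calendar year", years)
  combos <- dplyr::distinct(sens, .data$edh_index, .data$response)
  vars <- purrr::pmap(combos, function(edh_index, response) {
    ncdf4::ncvar_def(paste0("r_", edh_index, "_", response), "1",
                     list(dim_lon, dim_lat, dim_year), missval = 1e30,
                     prec = "float")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  purrr::pwalk(combos, function(edh_index, response) {
    slice <- sens[sens$edh_index == edh_index & sens$response == response, ]
    ncdf4::ncvar_put(nc, paste0("r_", edh_index, "_", response),
                     to_nc_array(slice, "r", g$lats, g$lons,
                                 "window_end_year")$arr)
  })
  nc_global_attrs(nc, c(list(package = "edhwheat",
                             method = sens$method[1],
                             dataset_variant = sens$dataset_variant[1]), attrs))
  invisible(path)
}

#' @rdname write_sensitivity_nc
#' @export
read_sensitivity_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  vnames <- names(nc$var)
  if (!length(grep("^r_", vnames))) {
    ncdf4::nc_close(nc)
    stop_schema("NetCDF file '%s' holds no sensitivity variables (r_*).", path)
  }
  lons <- nc$dim$lon$vals
  lats <- nc$dim$lat$vals
  years <- nc$dim$window_end_year$vals
  method <- ncdf4::ncatt_get(nc, 0, "method")
  variant <- ncdf4::ncatt_get(nc, 0, "dataset_variant")
  out <- purrr::map_dfr(grep("^r_", vnames, value = TRUE), function(v) {
    parts <- strsplit(sub("^r_", "", v), "_")[[1]]
    vals <- ncdf4::ncvar_get(nc, v)
    vals[vals > 1e29] <- NA_real_
    tidyr::expand_grid(window_end_year = years, lat = lats, lon = lons) |>
      dplyr::arrange(.data$window_end_year, .data$lat, .data$lon) |>
      dplyr::mutate(
        edh_index = parts[1],
        response = paste(parts[-1], collapse = "_"),
        r = as.vector(vals)
      )
  })
  ncdf4::nc_close(nc)
  out <- out |>
    dplyr::mutate(
      cell = grid_cell_id(.data$lat, .data$lon, lats, lons),
      method = if (method$hasatt) method$value else NA_character_,
      dataset_variant = if (variant$hasatt) variant$value else NA_character_
    ) |>
    dplyr::arrange(.data$edh_index, .data$response, .data$cell,
                   .data$window_end_year) |>
    dplyr::select("cell", "lat", "lon", "window_end_year", "edh_index",
                  "response", "method", "dataset_variant", "r")
  as_edh_tbl(out, "edh_sensitivity")
}

#' Read and write recommendation maps as NetCDF
#'
#' Per extreme-day index: an integer variable `rec_<index>` with codes 0
#' (none), 1 (NT), 2 (CT) and float32 frequency layers `freq_nt_<index>`,
#' `freq_ct_<index>`. The consensus layer is stored as `rec_consensus`.
#'
#' @param map `edh_recommendation` tibble.
#' @inheritParams write_climate_nc
#' @return `read_recommendation_nc()` returns an `edh_recommendation`
#'   tibble; the writer returns `path` invisibly.
#' @export
write_recommendation_nc <- function(map, path, attrs = list()) {
  check_columns(map, c("cell", "lat", "lon", "edh_index", "freq_nt",
                       "freq_ct", "recommendation"), "map")
  g <- require_regular_grid(map, "map")
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lats)
  codes <- c(none = 0L, NT = 1L, CT = 2L)
  indices <- unique(map$edh_index)
  vars <- list()
  for (ix in indices) {
    vars <- c(vars, list(ncdf4::ncvar_def(
      paste0("rec_", ix), "code 0=none 1=NT 2=CT", list(dim_lon, dim_lat),
      missval = -1L, prec = "integer"
    )))
    if (ix != "consensus") {
      vars <- c(vars, list(
        ncdf4::ncvar_def(paste0("freq_nt_", ix), "1", list(dim_lon, dim_lat),
                         missval = 1e30, prec = "float"),
        ncdf4::ncvar_def(paste0("freq_ct_", ix), "1", list(dim_lon, dim_lat),
                         missval = 1e30, prec = "float")
      ))
    }
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (ix in indices) {
    slice <- map[map$edh_index == ix, ]
    put2d <- function(v, value) {
      arr <- array(NA_real_, dim = c(length(g$lons), length(g$lats)))
      arr[cbind(match(slice$lon, g$lons), match(slice$lat, g$lats))] <- value
      ncdf4::ncvar_put(nc, v, arr)
    }
    put2d(paste0("rec_", ix), codes[slice$recommendation])
    if (ix != "consensus") {
      put2d(paste0("freq_nt_", ix), slice$freq_nt)
      put2d(paste0("freq_ct_", ix), slice$freq_ct)
    }
  }
  nc_global_attrs(nc, c(list(package = "edhwheat",
                             threshold = attr(map, "threshold") %||% NA,
                             response = attr(map, "response") %||% NA), attrs))
  invisible(path)
}

#' @rdname write_recommendation_nc
#' @export
read_recommendation_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  vnames <- grep("^rec_", names(nc$var), value = TRUE)
  if (!length(vnames)) {
    ncdf4::nc_close(nc)
    stop_schema("NetCDF file '%s' holds no recommendation variables (rec_*).",
                path)
  }
  lons <- nc$dim$lon$vals
  lats <- nc$dim$lat$vals
  labels <- c("none", "NT", "CT")
  out <- purrr::map_dfr(vnames, function(v) {
    ix <- sub("^rec_", "", v)
    rec <- as.vector(ncdf4::ncvar_get(nc, v))
    base <- tidyr::expand_grid(lat = lats, lon = lons) |>
      dplyr::arrange(.data$lat, .data$lon) |>
      dplyr::mutate(edh_index = ix, recommendation = labels[rec + 1L])
    if (ix != "consensus") {
      fn <- as.vector(ncdf4::ncvar_get(nc, paste0("freq_nt_", ix)))
      fc <- as.vector(ncdf4::ncvar_get(nc, paste0("freq_ct_", ix)))
      fn[fn > 1e29] <- NA_real_
      fc[fc > 1e29] <- NA_real_
      base$freq_nt <- fn
      base$freq_ct <- fc
    } else {
      base$freq_nt <- NA_real_
      base$freq_ct <- NA_real_
    }
    base
  })
  ncdf4::nc_close(nc)
  out <- out |>
    dplyr::mutate(cell = grid_cell_id(.data$lat, .data$lon, lats, lons)) |>
    dplyr::arrange(.data$cell, .data$edh_index) |>
    dplyr::select("cell", "lat", "lon", "edh_index", "freq_nt", "freq_ct",
                  "recommendation")
  as_edh_tbl(out, "edh_recommendation")
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' the synthetic experiment configuration plus the analysis constants. The
#' defaults are the package's standard analysis settings: 20-year moving
#' windows, a 30 °C heat-day threshold, a 0.2 aridity threshold, a 0.05
#' two-sided significance level, a 0.75 positive-effect threshold, all
#' three correlation methods and three climate dataset variants.
#'
#' `read_pipeline_config()` loads the same structure from a YAML file;
#' keys mirror the argument names, with synthetic generator fields under a
#' `synthetic:` block. Unknown keys raise a configuration error.
#'
#' @param synthetic An [synthetic_config()] (or a list of arguments for
#'   it).
#' @param window_length Moving-window length, years.
#' @param heat_threshold Heat-day threshold, °C.
#' @param aridity_threshold Dry-day aridity threshold.
#' @param alpha Two-sided significance level.
#' @param tillage_threshold Positive-effect frequency threshold.
#' @param methods Correlation methods to run (first = primary).
#' @param n_variants Number of climate dataset variants for the
#'   uncertainty analysis.
#' @param uncertainty_responses Responses included in the non-primary
#'   method runs (the uncertainty analysis targets the intensity by
#'   default).
#' @param seed Overrides the synthetic configuration's seed when given.
#' @return A list of class `edh_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            window_length = 20,
                            heat_threshold = 30,
                            aridity_threshold = 0.2,
                            alpha = 0.05,
                            tillage_threshold = 0.75,
                            methods = c("pearson", "kendall", "spearman"),
                            n_variants = 3,
                            uncertainty_responses = "ghgi",
                            seed = NULL) {
  if (!inherits(synthetic, "edh_config")) {
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  }
  if (!is.null(seed)) {
    synthetic$seed <- as.integer(seed)
  }
  methods <- match.arg(methods, c("pearson", "kendall", "spearman"),
                       several.ok = TRUE)
  if (window_length < 3) stop_config("`window_length` must be at least 3.")
  if (alpha <= 0 || alpha >= 1) stop_config("`alpha` must lie in (0, 1).")
  if (tillage_threshold < 0 || tillage_threshold > 1) {
    stop_config("`tillage_threshold` must lie in [0, 1].")
  }
  structure(list(
    synthetic = synthetic,
    window_length = window_length,
    heat_threshold = heat_threshold,
    aridity_threshold = aridity_threshold,
    alpha = alpha,
    tillage_threshold = tillage_threshold,
    methods = methods,
    n_variants = as.integer(n_variants),
    uncertainty_responses = uncertainty_responses
  ), class = "edh_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("synthetic", "window_length", "heat_threshold",
             "aridity_threshold", "alpha", "tillage_threshold", "methods",
             "n_variants", "uncertainty_responses", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_config("Unknown configuration key(s): %s.", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    for (f in c("beta_yield", "beta_fco2", "beta_fn2o", "beta_fch4",
                "noise_sd_response")) {
      if (!is.null(syn[[f]])) syn[[f]] <- unlist(syn[[f]])
    }
    for (f in c("years", "lat_range", "lon_range")) {
      if (!is.null(syn[[f]])) syn[[f]] <- unlist(syn[[f]])
    }
    raw$synthetic <- do.call(synthetic_config, syn)
  }
  do.call(pipeline_config, raw)
}
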