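# Internal helpers shared across modules.

# Condition helpers -----------------------------------------------------------

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "edhwheat_config_error")
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "edhwheat_input_error")
}

stop_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "edhwheat_schema_error")
}

# Column contract: every tibble-first function names the columns it needs.
check_columns <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    stop_input("`%s` must be a data frame, got <%s>.", what, class(x)[1])
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop_schema(
      "`%s` is missing required column(s): %s (required: %s).",
      what, paste(missing, collapse = ", "), paste(cols, collapse = ", ")
    )
  }
  invisible(x)
}

# RNG stream derivation --------------------------------------------------------
#
# One stream per (purpose, variant) pair, derived from the master seed so that
# adding a scenario or dataset variant never perturbs draws used elsewhere.
# Purpose codes are fixed; the arithmetic keeps the derived seed in (0, 2^31).
.stream_codes <- c(
  tmax_noise     = 11L,
  annual_anomaly = 17L,
  diurnal_range  = 23L,
  precip_occ     = 29L,
  precip_amt     = 31L,
  response_noise = 41L
)

edh_stream <- function(seed, purpose, variant = 1L) {
  code <- .stream_codes[[purpose]]
  if (is.null(code)) stop_input("Unknown RNG stream purpose '%s'.", purpose)
  as.integer((as.double(seed) * 48271 + code * 75913 + variant * 452807) %%
               2147483587) + 1L
}

with_stream <- function(seed, purpose, variant, code) {
  withr::with_seed(edh_stream(seed, purpose, variant), code)
}

# Misc -------------------------------------------------------------------------

# Spherical cell area (km^2) of a regular lat/lon cell centred at `lat`.
cell_area_km2 <- function(lat, dlat, dlon) {
  r_earth <- 6371.0088
  lat1 <- pmax(-90, lat - dlat / 2) * pi / 180
  lat2 <- pmin(90, lat + dlat / 2) * pi / 180
  r_earth^2 * (dlon * pi / 180) * (sin(lat2) - sin(lat1))
}

# Subclass a tibble without disturbing the tbl_df machinery.
as_edh_tbl <- function(x, subclass) {
  x <- tibble::as_tibble(x)
  class(x) <- c(subclass, class(x))
  x
}
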