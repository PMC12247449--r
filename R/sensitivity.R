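#' Linear detrending of an annual series
#'
#' Residuals from the ordinary least squares fit of the series on time.
#' Removing the full-period linear trend before windowed correlation keeps
#' slow co-trends (warming, technology) from masquerading as year-to-year
#' coupling. Missing values stay missing; the fit uses the available years.
#' A constant series detrends to all zeros.
#'
#' @param y Numeric series (annual values).
#' @param t Time axis; defaults to the observation index.
#' @return Residual series, same length as `y`, with zero mean and zero OLS
#'   slope over the non-missing entries.
#' @examples
#' detrend_linear(3 * (1:10) + rnorm(10))
#' @export
detrend_linear <- function(y, t = seq_along(y)) {
  if (length(y) < 3) stop_input("Need at least 3 values to detrend.")
  ok <- !is.na(y) & !is.na(t)
  out <- rep(NA_real_, length(y))
  if (sum(ok) < 2 || stats::var(t[ok]) == 0) {
    out[ok] <- y[ok] - mean(y[ok])
    return(out)
  }
  tc <- t[ok] - mean(t[ok])
  beta <- sum(tc * y[ok]) / sum(tc^2)
  out[ok] <- y[ok] - mean(y[ok]) - beta * tc
  out
}

# Rolling Pearson correlation via cumulative sums. A window is NA when it
# contains a missing value (tracked separately so later windows recover) or
# when either side has zero variance within it.
rolling_pearson <- function(x, y, window) {
  n <- length(x)
  bad <- is.na(x) | is.na(y)
  x0 <- ifelse(bad, 0, x)
  y0 <- ifelse(bad, 0, y)
  cs <- function(v) cumsum(c(0, v))
  sx <- cs(x0); sy <- cs(y0)
  sxx <- cs(x0^2); syy <- cs(y0^2); sxy <- cs(x0 * y0)
  nbad <- cs(bad)
  i <- window:n
  w <- window
  take <- function(s) s[i + 1] - s[i + 1 - w]
  Sx <- take(sx); Sy <- take(sy)
  Sxx <- take(sxx); Syy <- take(syy); Sxy <- take(sxy)
  num <- w * Sxy - Sx * Sy
  den2 <- (w * Sxx - Sx^2) * (w * Syy - Sy^2)
  r <- ifelse(take(nbad) > 0 | den2 <= 0, NA_real_, num / sqrt(pmax(den2, 1e-300)))
  # cumulative sums can leak tiny float error past +-1
  pmin(1, pmax(-1, r))
}

rolling_rank_cor <- function(x, y, window, method) {
  n <- length(x)
  vapply(window:n, function(e) {
    xs <- x[(e - window + 1):e]
    ys <- y[(e - window + 1):e]
    if (anyNA(xs) || anyNA(ys) ||
        stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys, method = method)
  }, numeric(1))
}

#' Moving-window correlation between two annual series
#'
#' Correlation between `x` and `y` over every contiguous window of
#' `window` years, labelled by the window's final year (so with a 20-year
#' window the first label is the 20th year). Windows containing missing
#' values, or in which either series has zero variance, yield `NA`.
#' Detrend the inputs first (see [detrend_linear()]) if trend leakage is a
#' concern; this function correlates the series exactly as given.
#'
#' @param x,y Equal-length numeric series (e.g. an extreme-day index and a
#'   response), ordered by year.
#' @param years Optional year labels aligned with the series; defaults to
#'   the index.
#' @param window Window length in years, at least 3.
#' @param method `"pearson"`, `"kendall"` or `"spearman"`.
#' @return Tibble with `window_end_year` and `r`
#'   (`length(x) - window + 1` rows).
#' @examples
#' moving_window_correlation(rnorm(30), rnorm(30), window = 20)
#' @export
moving_window_correlation <- function(x, y, years = seq_along(x), window = 20,
                                      method = c("pearson", "kendall", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_input("`x` and `y` differ in length.")
  if (window < 3) stop_input("`window` must be at least 3 years.")
  if (window > length(x)) stop_input("`window` exceeds the series length.")
  r <- if (method == "pearson") rolling_pearson(x, y, window)
       else rolling_rank_cor(x, y, window, method)
  tibble::tibble(window_end_year = years[window:length(x)], r = r)
}

#' Gridded moving-window sensitivity of responses to extreme-day indices
#'
#' For every cell, detrends (full-period) each extreme-day index and each
#' response series, then computes the moving-window correlation between all
#' index–response pairs. The correlation's sign is the direction of the
#' sensitivity, its magnitude the strength; results are labelled by the
#' window's final year.
#'
#' @param edh `edh_field` tibble (columns `hc`, `dc`, `cdhc`).
#' @param responses Tibble with `cell`, `year` and the response columns.
#' @param response_vars Response columns to use (defaults to whichever of
#'   `yield`, `eghg`, `ghgi` are present).
#' @param window Window length in years.
#' @param method Correlation method, as in [moving_window_correlation()].
#' @param detrend Detrend scope: `"full"` (default) removes the full-period
#'   linear trend once before windowing; `"window"` detrends within each
#'   window (equivalent to correlating windowed residuals of local fits);
#'   `"none"` correlates raw series.
#' @param dataset_variant Label recorded in the output (climate-dataset
#'   provenance of the index side).
#' @return Tibble of class `edh_sensitivity`: `cell`, `lat`, `lon`,
#'   `window_end_year`, `edh_index`, `response`, `method`,
#'   `dataset_variant`, `r`.
#' @examples
#' cfg <- synthetic_config(n_lat = 2, n_lon = 2, years = c(1990, 2018))
#' edh <- compute_edh_field(generate_daily_climate(cfg))
#' resp <- ghg_intensity(generate_scenario_outputs(edh, cfg, "S2"))
#' sens <- edh_sensitivity(edh, resp, window = 20)
#' @export
edh_sensitivity <- function(edh, responses, response_vars = NULL, window = 20,
                            method = c("pearson", "kendall", "spearman"),
                            detrend = c("full", "window", "none"),
                            dataset_variant = "primary") {
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  check_columns(edh, c("cell", "lat", "lon", "year", "hc", "dc", "cdhc"), "edh")
  check_columns(responses, c("cell", "year"), "responses")
  response_vars <- response_vars %||%
    intersect(c("yield", "eghg", "ghgi"), names(responses))
  if (!length(response_vars)) stop_input("No response columns found.")
  check_columns(responses, response_vars, "responses")

  e <- dplyr::arrange(edh, .data$cell, .data$year)
  rsp <- dplyr::arrange(responses[, c("cell", "year", response_vars)],
                        .data$cell, .data$year)
  check_matching_grids(e[, c("cell", "year")], rsp[, c("cell", "year")],
                       "edh", "responses")
  years <- sort(unique(e$year))
  if (window > length(years)) stop_input("`window` exceeds the year span.")
  cells <- unique(e$cell)
  coords <- e[!duplicated(e$cell), c("cell", "lat", "lon")]

  prep <- function(v, tbl) {
    m <- matrix(tbl[[v]], nrow = length(years))  # years x cells
    if (detrend == "full") m <- apply(m, 2, detrend_linear, t = years)
    m
  }
  idx_mats <- lapply(stats::setNames(nm = c("hc", "dc", "cdhc")), prep, tbl = e)
  rsp_mats <- lapply(stats::setNames(nm = response_vars), prep, tbl = rsp)

  window_detrend_cor <- function(x, y) {
    vapply(window:length(x), function(end) {
      xs <- x[(end - window + 1):end]; ys <- y[(end - window + 1):end]
      if (anyNA(xs) || anyNA(ys)) return(NA_real_)
      xs <- detrend_linear(xs); ys <- detrend_linear(ys)
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
      stats::cor(xs, ys, method = method)
    }, numeric(1))
  }

  ends <- years[window:length(years)]
  combos <- tidyr::expand_grid(edh_index = c("hc", "dc", "cdhc"),
                               response = response_vars)
  out <- purrr::pmap_dfr(combos, function(edh_index, response) {
    xm <- idx_mats[[edh_index]]
    ym <- rsp_mats[[response]]
    r <- vapply(seq_along(cells), function(ci) {
      if (detrend == "window") window_detrend_cor(xm[, ci], ym[, ci])
      else if (method == "pearson") rolling_pearson(xm[, ci], ym[, ci], window)
      else rolling_rank_cor(xm[, ci], ym[, ci], window, method)
    }, numeric(length(ends)))
    tibble::tibble(
      cell = rep(cells, each = length(ends)),
      window_end_year = rep(ends, times = length(cells)),
      edh_index = edh_index, response = response,
      r = as.vector(r)
    )
  })
  out <- dplyr::left_join(out, coords, by = "cell") |>
    dplyr::mutate(method = method, dataset_variant = dataset_variant) |>
    dplyr::select("cell", "lat", "lon", "window_end_year", "edh_index",
                  "response", "method", "dataset_variant", "r")
  as_edh_tbl(out, "edh_sensitivity")
}

new_edh_trend <- function(method, slope, statistic, p_value, n, alpha) {
  p_value <- min(1, max(0, p_value))
  out <- tibble::tibble(
    method = method, slope = slope, statistic = statistic,
    p_value = p_value, significant = p_value < alpha, n = n, alpha = alpha
  )
  as_edh_tbl(out, "edh_trend")
}

#' Per-grid linear trend of a sensitivity series
#'
#' Ordinary least squares slope of the windowed correlation against the
#' window end year, with a two-sided t-test on the slope. A constant series
#' gives slope 0 with p = 1 (nothing to detect); an exact non-zero linear
#' drift gives p = 0.
#'
#' @param r Correlation series (one cell, ordered by window end year).
#' @param years Window end years aligned with `r`.
#' @param alpha Two-sided significance level.
#' @return One-row tibble of class `edh_trend`: `method` (`"ols"`),
#'   `slope` (change of R per year), `statistic` (t), `p_value`,
#'   `significant`, `n`, `alpha`.
#' @examples
#' grid_sensitivity_trend(seq(0.1, 0.5, length.out = 40) + rnorm(40, 0, 0.05))
#' @export
grid_sensitivity_trend <- function(r, years = seq_along(r), alpha = 0.05) {
  ok <- !is.na(r)
  n <- sum(ok)
  if (n < 3) stop_input("Need at least 3 non-missing values for a trend.")
  t_ <- years[ok] - mean(years[ok])
  y <- r[ok]
  sxx <- sum(t_^2)
  if (sxx == 0) stop_input("Degenerate time axis.")
  slope <- sum(t_ * y) / sxx
  res <- y - mean(y) - slope * t_
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  if (se == 0) {
    p <- if (abs(slope) < .Machine$double.eps^0.5) 1 else 0
    tstat <- if (p == 1) 0 else Inf * sign(slope)
  } else {
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_edh_trend("ols", slope, tstat, p, n, alpha)
}

#' Mann–Kendall trend test with Sen slope
#'
#' Nonparametric monotone-trend test for a regional series: the statistic
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)} with tie-corrected variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_p t_p(t_p-1)(2t_p+5)]/18},
#' a normal approximation with continuity correction, and a two-sided
#' p-value. The slope is the Theil–Sen estimator (median of pairwise
#' slopes). No distributional assumption on the series is required.
#'
#' @param x Numeric series (e.g. the regional median sensitivity by window
#'   end year), at least 3 values; 8+ recommended for the normal
#'   approximation.
#' @param years Time axis for the Sen slope; defaults to the index.
#' @param alpha Two-sided significance level.
#' @return One-row tibble of class `edh_trend`: `method`
#'   (`"mann_kendall"`), `slope` (Sen), `statistic` (S), `p_value`,
#'   `significant`, `n`, `alpha`.
#' @examples
#' mann_kendall_trend(cumsum(rnorm(40)))
#' @export
mann_kendall_trend <- function(x, years = seq_along(x), alpha = 0.05) {
  ok <- !is.na(x)
  x <- x[ok]; years <- years[ok]
  n <- length(x)
  if (n < 3) stop_input("Need at least 3 non-missing values for Mann-Kendall.")
  dx <- outer(x, x, "-")       # dx[j, i] = x_j - x_i
  lower <- lower.tri(dx)       # rows j > columns i, i.e. all i < j pairs
  s <- sum(sign(dx[lower]))
  ties <- table(x)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s <= 0) 0
       else if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  p <- 2 * stats::pnorm(-abs(z))
  dt <- outer(years, years, "-")
  sen <- stats::median(dx[lower] / dt[lower], na.rm = TRUE)
  new_edh_trend("mann_kendall", sen, s, p, n, alpha)
}

# Grouped-safe trend columns: series too short for a test give NA columns
# instead of an error (dplyr also evaluates summaries on an empty prototype).
trend_summary_cols <- function(fun, x, years, alpha) {
  if (sum(!is.na(x)) < 3) {
    return(tibble::tibble(slope = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, significant = NA,
                          n = sum(!is.na(x))))
  }
  tr <- fun(x, years, alpha)
  tr[, c("slope", "statistic", "p_value", "significant", "n")]
}

#' Gridded sensitivity trends
#'
#' Applies [grid_sensitivity_trend()] to every (cell, index, response,
#' method, variant) series of a sensitivity field. Series with fewer than
#' three non-missing windows get `NA` trend columns.
#'
#' @param sens `edh_sensitivity` tibble.
#' @param alpha Two-sided significance level.
#' @return Tibble with one row per series and columns `slope`, `statistic`,
#'   `p_value`, `significant`, `n`.
#' @export
sensitivity_trends <- function(sens, alpha = 0.05) {
  check_columns(sens, c("cell", "window_end_year", "edh_index", "response", "r"),
                "sens")
  sens |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("cell", "lat", "lon", "edh_index", "response", "method",
        "dataset_variant")))) |>
    dplyr::arrange(.data$window_end_year, .by_group = TRUE) |>
    dplyr::summarise(
      trend_summary_cols(grid_sensitivity_trend, .data$r,
                         .data$window_end_year, alpha),
      .groups = "drop"
    )
}

#' Uncertainty of sensitivity across dataset and method combinations
#'
#' Mean, standard deviation and standard error \eqn{SE = s/\sqrt{n}} of the
#' windowed correlation across dataset × method combinations, per (cell,
#' window, index, response). With the full design of three meteorological
#' dataset variants and three correlation methods, `n = 9`.
#'
#' @param fields An `edh_sensitivity` tibble holding several
#'   (`method`, `dataset_variant`) combinations, or a list of such tibbles
#'   (bound together first).
#' @return Tibble with `cell`, `lat`, `lon`, `window_end_year`,
#'   `edh_index`, `response`, `n`, `mean_r`, `s`, `se`.
#' @export
uncertainty_across_combinations <- function(fields) {
  if (is.data.frame(fields)) fields <- list(fields)
  x <- dplyr::bind_rows(fields)
  check_columns(x, c("cell", "window_end_year", "edh_index", "response",
                     "method", "dataset_variant", "r"), "fields")
  n_combo <- nrow(dplyr::distinct(x, .data$method, .data$dataset_variant))
  if (n_combo < 2) {
    stop_input("Need at least 2 method x dataset combinations, got %d.", n_combo)
  }
  x |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("cell", "lat", "lon", "window_end_year", "edh_index", "response")))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$r)),
      mean_r = mean(.data$r, na.rm = TRUE),
      s = stats::sd(.data$r, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = .data$s / sqrt(.data$n))
}

#' Regional summary of a sensitivity field
#'
#' Spatial median of the windowed correlation and the share of cells with
#' positive / negative sensitivity, per window (and per index, response,
#' method, variant). Missing correlations (masked cell-years, zero-variance
#' windows) are excluded from both the median and the shares.
#'
#' @param sens `edh_sensitivity` tibble.
#' @param mask Optional vector of cell ids to include.
#' @return Tibble with `edh_index`, `response`, `method`,
#'   `dataset_variant`, `window_end_year`, `n_cells`, `median_r`,
#'   `frac_positive`, `frac_negative`.
#' @export
regional_summary <- function(sens, mask = NULL) {
  check_columns(sens, c("cell", "window_end_year", "edh_index", "response", "r"),
                "sens")
  x <- if (is.null(mask)) sens else dplyr::filter(sens, .data$cell %in% mask)
  x |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("edh_index", "response", "method", "dataset_variant",
        "window_end_year")))) |>
    dplyr::summarise(
      n_cells = sum(!is.na(.data$r)),
      median_r = stats::median(.data$r, na.rm = TRUE),
      frac_positive = mean(.data$r > 0, na.rm = TRUE),
      frac_negative = mean(.data$r < 0, na.rm = TRUE),
      .groups = "drop"
    )
}
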