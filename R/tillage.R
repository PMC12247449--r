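#' Classify a tillage-induced sensitivity difference
#'
#' Sign rules for the effect of a tillage counterfactual on the windowed
#' sensitivity, with `d` the tillage-minus-actual correlation difference:
#' for yield a positive difference is a positive effect (PE) and a negative
#' one a negative effect (NE); for GHG emissions and GHGI the signs flip
#' (more positive coupling of emissions to dry-heat is adverse). A zero
#' difference is neutral and returns `NA`: the rules define labels only for
#' strict inequalities, and neutral windows are excluded from both the
#' numerator and denominator of the positive-effect frequency.
#'
#' @param d Numeric sensitivity difference(s), tillage minus actual.
#' @param variable `"yield"`, `"ghg"` or `"ghgi"` (the response the
#'   difference was computed on; `"eghg"` is accepted as an alias of
#'   `"ghg"`).
#' @return Character vector in `"PE"`, `"NE"`, `NA`.
#' @examples
#' effect_classify(c(0.1, -0.1, 0), "ghgi")
#' @export
effect_classify <- function(d, variable) {
  variable <- match.arg(variable, c("yield", "ghg", "ghgi", "eghg"))
  flip <- variable %in% c("ghg", "eghg", "ghgi")
  out <- dplyr::case_when(
    is.na(d) | d == 0 ~ NA_character_,
    xor(d > 0, flip) ~ "PE",
    TRUE ~ "NE"
  )
  out
}

#' Positive-effect frequency across moving windows
#'
#' Fraction of labelled windows classified as positive effects,
#' `count(PE) / count(PE or NE)`. Neutral (`NA`) windows do not enter the
#' ratio; a series with no labelled window returns `NA`.
#'
#' @param labels Character vector of `"PE"` / `"NE"` / `NA` labels, as from
#'   [effect_classify()].
#' @return Fraction in \eqn{[0, 1]}, or `NA`.
#' @examples
#' positive_effect_frequency(c("PE", "PE", "NE", NA))
#' @export
positive_effect_frequency <- function(labels) {
  n <- sum(!is.na(labels))
  if (n == 0) return(NA_real_)
  sum(labels == "PE", na.rm = TRUE) / n
}

#' Windowed tillage effects on sensitivity
#'
#' Joins a tillage-scenario sensitivity field with the actual-scenario
#' field and computes, per cell, window, index and response, the difference
#' `d = r_tillage - r_actual` and its PE/NE label.
#'
#' @param actual,tillage `edh_sensitivity` tibbles on the same grid,
#'   windows, indices and responses (same method and dataset variant).
#' @param scenario `"NT"` or `"CT"` label recorded in the output.
#' @return Tibble of class `edh_tillage_effect`: `cell`, `lat`, `lon`,
#'   `window_end_year`, `edh_index`, `response`, `scenario`, `d`, `label`.
#' @export
tillage_effects <- function(actual, tillage, scenario = c("NT", "CT")) {
  scenario <- match.arg(scenario)
  cols <- c("cell", "lat", "lon", "window_end_year", "edh_index", "response", "r")
  check_columns(actual, cols, "actual")
  check_columns(tillage, cols, "tillage")
  key <- c("cell", "lat", "lon", "window_end_year", "edh_index", "response")
  joined <- dplyr::inner_join(
    dplyr::rename(actual[, cols], r_actual = "r"),
    dplyr::rename(tillage[, cols], r_tillage = "r"),
    by = key
  )
  if (nrow(joined) != nrow(actual)) {
    stop_input("`actual` and `tillage` sensitivity fields do not align.")
  }
  out <- joined |>
    dplyr::mutate(
      scenario = scenario,
      d = .data$r_tillage - .data$r_actual,
      label = dplyr::if_else(
        .data$response == "yield",
        effect_classify(.data$d, "yield"),
        effect_classify(.data$d, "ghgi")
      )
    ) |>
    dplyr::select(dplyr::all_of(key), "scenario", "d", "label")
  as_edh_tbl(out, "edh_tillage_effect")
}

#' Tillage recommendation from positive-effect frequencies
#'
#' Decision rule for one cell (vectorised): no recommendation when neither
#' scenario's positive-effect frequency strictly exceeds the threshold; the
#' single qualifying scenario otherwise; the higher-frequency scenario when
#' both qualify, with exact ties broken toward no-till (the
#' emission-reduction default; configurable via `tie`).
#'
#' @param freq_nt,freq_ct Positive-effect frequencies in \eqn{[0, 1]}
#'   (`NA` treated as not qualifying).
#' @param threshold Strict qualification threshold.
#' @param tie `"NT"` or `"CT"`: winner on exact ties when both qualify.
#' @return Character vector in `"NT"`, `"CT"`, `"none"`.
#' @examples
#' recommend_tillage(c(0.8, 0.75, 0.9, 0.8), c(0.6, 0.75, 0.8, 0.8))
#' @export
recommend_tillage <- function(freq_nt, freq_ct, threshold = 0.75,
                              tie = c("NT", "CT")) {
  tie <- match.arg(tie)
  f_nt <- dplyr::coalesce(freq_nt, -Inf)
  f_ct <- dplyr::coalesce(freq_ct, -Inf)
  nt_ok <- f_nt > threshold
  ct_ok <- f_ct > threshold
  dplyr::case_when(
    !nt_ok & !ct_ok ~ "none",
    nt_ok & !ct_ok ~ "NT",
    ct_ok & !nt_ok ~ "CT",
    f_nt > f_ct ~ "NT",
    f_ct > f_nt ~ "CT",
    TRUE ~ tie
  )
}

#' Environment-specific tillage recommendation map
#'
#' Computes NT and CT effects against the actual scenario, their
#' positive-effect frequencies across all moving windows, the per-cell
#' recommendation per extreme-day index, whether the recommended scenario
#' is positive in every window (full mitigation), and a consensus map
#' (majority recommendation across the three indices, `"none"` when no
#' majority).
#'
#' @param actual,nt,ct `edh_sensitivity` tibbles for the actual, all-NT and
#'   all-CT scenarios (same grid, method, variant).
#' @param response Response variable the recommendation targets (the
#'   mitigation target; default `"ghgi"`).
#' @param threshold Strict positive-effect frequency threshold.
#' @param tie Tie-break scenario passed to [recommend_tillage()].
#' @return Tibble of class `edh_recommendation`: `cell`, `lat`, `lon`,
#'   `edh_index` (`hc`, `dc`, `cdhc`, `consensus`), `freq_nt`, `freq_ct`,
#'   `recommendation`, `full_mitigation`.
#' @export
recommendation_map <- function(actual, nt, ct, response = "ghgi",
                               threshold = 0.75, tie = "NT") {
  eff <- dplyr::bind_rows(
    tillage_effects(actual, nt, "NT"),
    tillage_effects(actual, ct, "CT")
  ) |>
    dplyr::filter(.data$response == !!response)
  if (!nrow(eff)) stop_input("Response '%s' not present in the fields.", response)

  freqs <- eff |>
    dplyr::group_by(.data$cell, .data$lat, .data$lon, .data$edh_index,
                    .data$scenario) |>
    dplyr::summarise(
      freq = positive_effect_frequency(.data$label),
      full = sum(!is.na(.data$label)) > 0 && all(.data$label == "PE", na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "scenario", values_from = c("freq", "full"))

  per_index <- freqs |>
    dplyr::mutate(
      recommendation = recommend_tillage(.data$freq_NT, .data$freq_CT,
                                         threshold = threshold, tie = tie),
      full_mitigation = dplyr::case_when(
        .data$recommendation == "NT" ~ .data$full_NT,
        .data$recommendation == "CT" ~ .data$full_CT,
        TRUE ~ FALSE
      )
    ) |>
    dplyr::select("cell", "lat", "lon", "edh_index",
                  freq_nt = "freq_NT", freq_ct = "freq_CT",
                  "recommendation", "full_mitigation")

  consensus <- per_index |>
    dplyr::group_by(.data$cell, .data$lat, .data$lon) |>
    dplyr::summarise(
      edh_index = "consensus",
      freq_nt = NA_real_, freq_ct = NA_real_,
      recommendation = dplyr::case_when(
        sum(.data$recommendation == "NT") >= 2 ~ "NT",
        sum(.data$recommendation == "CT") >= 2 ~ "CT",
        TRUE ~ "none"
      ),
      full_mitigation = FALSE,
      .groups = "drop"
    )

  out <- dplyr::bind_rows(per_index, consensus) |>
    dplyr::arrange(.data$cell, .data$edh_index)
  out <- as_edh_tbl(out, "edh_recommendation")
  attr(out, "threshold") <- threshold
  attr(out, "response") <- response
  out
}

#' Apply a recommendation map to sensitivity fields
#'
#' Builds the "optimal tillage" sensitivity field: per cell and index, the
#' recommended scenario's correlation series where a recommendation exists,
#' the actual series elsewhere. The operation is cellwise-local and
#' idempotent.
#'
#' @inheritParams recommendation_map
#' @param map `edh_recommendation` tibble from [recommendation_map()].
#' @return `edh_sensitivity` tibble with the same shape as `actual`.
#' @export
apply_recommendation <- function(actual, nt, ct, map) {
  cols <- c("cell", "window_end_year", "edh_index", "response", "r")
  check_columns(actual, cols, "actual")
  check_columns(map, c("cell", "edh_index", "recommendation"), "map")
  key <- c("cell", "edh_index")
  rec <- map[map$edh_index != "consensus", c(key, "recommendation")]
  out <- actual |>
    dplyr::left_join(rec, by = key) |>
    dplyr::left_join(
      dplyr::select(nt, dplyr::all_of(cols)) |> dplyr::rename(r_nt = "r"),
      by = setdiff(cols, "r")
    ) |>
    dplyr::left_join(
      dplyr::select(ct, dplyr::all_of(cols)) |> dplyr::rename(r_ct = "r"),
      by = setdiff(cols, "r")
    ) |>
    dplyr::mutate(
      r = dplyr::case_when(
        .data$recommendation == "NT" ~ .data$r_nt,
        .data$recommendation == "CT" ~ .data$r_ct,
        TRUE ~ .data$r
      )
    ) |>
    dplyr::select(-"recommendation", -"r_nt", -"r_ct")
  as_edh_tbl(out, "edh_sensitivity")
}

#' Sensitivity reduction achieved by the recommended tillage scheme
#'
#' Quantifies, per extreme-day index, how much the environment-specific
#' scheme lowers the regional dry-heat sensitivity in the recommended
#' cells: for each window the spatial median of the actual and optimal
#' correlations over the recommended cells is taken, the relative change
#' \eqn{100 (\tilde R_{act} - \tilde R_{opt}) / |\tilde R_{act}|} is
#' computed, and the window values are averaged. Windows whose actual
#' median magnitude falls below `min_median` are undefined and excluded.
#' This aggregation (regional median, relative change, window-averaged) is
#' one explicit reconstruction of a reduction statistic; see the methods
#' vignette for the reasoning.
#'
#' @param actual,optimal `edh_sensitivity` tibbles (optimal as from
#'   [apply_recommendation()]).
#' @param map `edh_recommendation` tibble; per index, only cells with a
#'   recommendation enter the medians.
#' @param response Response to aggregate (default the mitigation target,
#'   `"ghgi"`).
#' @param min_median Guard on the actual median magnitude.
#' @return Tibble of class `edh_reduction`: `edh_index`, `reduction_pct`,
#'   `n_cells`, `n_windows`. `glance()` gives the mean and range across
#'   indices.
#' @export
sensitivity_reduction <- function(actual, optimal, map, response = "ghgi",
                                  min_median = 1e-6) {
  cols <- c("cell", "window_end_year", "edh_index", "response", "r")
  check_columns(actual, cols, "actual")
  check_columns(optimal, cols, "optimal")
  check_columns(map, c("cell", "edh_index", "recommendation"), "map")
  rec <- map[map$edh_index != "consensus" & map$recommendation != "none",
             c("cell", "edh_index")]
  a <- dplyr::semi_join(
    dplyr::filter(actual, .data$response == !!response), rec,
    by = c("cell", "edh_index")
  )
  o <- dplyr::semi_join(
    dplyr::filter(optimal, .data$response == !!response), rec,
    by = c("cell", "edh_index")
  )
  joined <- dplyr::inner_join(
    dplyr::rename(a[, cols], r_actual = "r"),
    dplyr::rename(o[, cols], r_optimal = "r"),
    by = setdiff(cols, "r")
  )
  out <- joined |>
    dplyr::group_by(.data$edh_index, .data$window_end_year) |>
    dplyr::summarise(
      med_a = stats::median(.data$r_actual, na.rm = TRUE),
      med_o = stats::median(.data$r_optimal, na.rm = TRUE),
      n_cells = dplyr::n_distinct(.data$cell),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      red = dplyr::if_else(abs(.data$med_a) < min_median, NA_real_,
                           100 * (.data$med_a - .data$med_o) / abs(.data$med_a))
    ) |>
    dplyr::group_by(.data$edh_index) |>
    dplyr::summarise(
      reduction_pct = mean(.data$red, na.rm = TRUE),
      n_cells = max(.data$n_cells),
      n_windows = sum(!is.na(.data$red)),
      .groups = "drop"
    )
  as_edh_tbl(out, "edh_reduction")
}

#' Temporal trajectory of tillage effects
#'
#' Per cell, index and response: the OLS trend of the tillage-minus-actual
#' sensitivity difference across window end years, together with the
#' effect status (PE/NE label) in the final window. A drifting `d` series
#' shows whether positive effects are diminishing or negative effects
#' deteriorating over time.
#'
#' @param effects `edh_tillage_effect` tibble from [tillage_effects()].
#' @param alpha Two-sided significance level for the OLS trend.
#' @return Tibble with `cell`, `lat`, `lon`, `edh_index`, `response`,
#'   `scenario`, `slope`, `p_value`, `significant`, `status`.
#' @export
effect_trajectory <- function(effects, alpha = 0.05) {
  check_columns(effects, c("cell", "window_end_year", "edh_index", "response",
                           "scenario", "d", "label"), "effects")
  effects |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("cell", "lat", "lon", "edh_index", "response", "scenario")))) |>
    dplyr::arrange(.data$window_end_year, .by_group = TRUE) |>
    dplyr::summarise(
      {
        tr <- trend_summary_cols(grid_sensitivity_trend, .data$d,
                                 .data$window_end_year, alpha)
        labs <- .data$label
        lab_idx <- which(!is.na(labs))
        status <- if (length(lab_idx)) labs[max(lab_idx)] else NA_character_
        tibble::tibble(slope = tr$slope, p_value = tr$p_value,
                       significant = tr$significant, status = status)
      },
      .groups = "drop"
    )
}
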