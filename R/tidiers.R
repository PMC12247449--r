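# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trend test result
#'
#' One row per tested series with the estimate and test columns named the
#' broom way (`estimate`, `statistic`, `p.value`).
#'
#' @param x An `edh_trend` from [grid_sensitivity_trend()] or
#'   [mann_kendall_trend()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.edh_trend <- function(x, ...) {
  tibble::tibble(
    term = "trend",
    method = x$method,
    estimate = x$slope,
    statistic = x$statistic,
    p.value = x$p_value
  )
}

#' @rdname tidy.edh_trend
#' @export
glance.edh_trend <- function(x, ...) {
  tibble::tibble(
    method = x$method, slope = x$slope, p.value = x$p_value,
    significant = x$significant, n = x$n, alpha = x$alpha
  )
}

#' Glance at model-evaluation metrics
#'
#' @param x An `edh_fit` from [fit_metrics()].
#' @param ... Unused.
#' @return A one-row tibble with `r2`, `rmse`, `nrmse`, `n`.
#' @export
glance.edh_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("r2", "rmse", "nrmse", "n")])
}

#' Tidy / summarise a sensitivity-reduction result
#'
#' `tidy()` returns the per-index reductions; `glance()` the mean and
#' range across the three extreme-day indices (the headline summary).
#'
#' @param x An `edh_reduction` from [sensitivity_reduction()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.edh_reduction <- function(x, ...) {
  tibble::tibble(
    term = x$edh_index,
    estimate = x$reduction_pct,
    n_cells = x$n_cells,
    n_windows = x$n_windows
  )
}

#' @rdname tidy.edh_reduction
#' @export
glance.edh_reduction <- function(x, ...) {
  tibble::tibble(
    mean_reduction_pct = mean(x$reduction_pct, na.rm = TRUE),
    min_reduction_pct = min(x$reduction_pct, na.rm = TRUE),
    max_reduction_pct = max(x$reduction_pct, na.rm = TRUE),
    n_indices = sum(!is.na(x$reduction_pct))
  )
}

#' Tidy a recommendation map
#'
#' Per index: counts and area shares of each recommendation category.
#'
#' @param x An `edh_recommendation` from [recommendation_map()].
#' @param ... Unused.
#' @return A tibble with `edh_index`, `recommendation`, `n_cells`,
#'   `share`.
#' @export
tidy.edh_recommendation <- function(x, ...) {
  x |>
    dplyr::count(.data$edh_index, .data$recommendation, name = "n_cells") |>
    dplyr::group_by(.data$edh_index) |>
    dplyr::mutate(share = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}

#' @rdname tidy.edh_recommendation
#' @export
glance.edh_recommendation <- function(x, ...) {
  per <- x[x$edh_index != "consensus", ]
  tibble::tibble(
    threshold = attr(x, "threshold") %||% NA_real_,
    response = attr(x, "response") %||% NA_character_,
    recommended_share = mean(per$recommendation != "none"),
    nt_share_of_recommended =
      sum(per$recommendation == "NT") / max(1, sum(per$recommendation != "none")),
    full_mitigation_share = mean(per$full_mitigation)
  )
}
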