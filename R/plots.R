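# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map the mean annual extreme-day counts
#'
#' Tile maps of the period-mean heat (HC), dry (DC) and compound dry-heat
#' (CDHC) day counts per cell.
#'
#' @param object An `edh_field` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edh_field <- function(object, ...) {
  means <- object |>
    tidyr::pivot_longer(c("hc", "dc", "cdhc"), names_to = "edh_index",
                        values_to = "days") |>
    dplyr::group_by(.data$lat, .data$lon, .data$edh_index) |>
    dplyr::summarise(days = mean(.data$days), .groups = "drop") |>
    dplyr::mutate(edh_index = factor(toupper(.data$edh_index),
                                     levels = c("HC", "DC", "CDHC")))
  ggplot2::ggplot(means, ggplot2::aes(.data$lon, .data$lat, fill = .data$days)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$edh_index)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "days/yr") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Mean annual extreme dry-heat day counts (Mar-Sep)")
}

#' Plot regional sensitivity trajectories
#'
#' Spatial-median windowed correlation against window end year, one line
#' per extreme-day index, faceted by response.
#'
#' @param object An `edh_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edh_sensitivity <- function(object, ...) {
  reg <- regional_summary(object)
  ggplot2::ggplot(reg, ggplot2::aes(.data$window_end_year, .data$median_r,
                                    colour = toupper(.data$edh_index))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$response), scales = "free_y") +
    ggplot2::labs(x = "Window end year", y = "Median correlation R",
                  colour = "EDH index",
                  title = "Moving-window sensitivity to extreme dry-heat")
}

#' Map tillage recommendations
#'
#' Categorical tile map of the recommended practice per cell, faceted by
#' extreme-day index (including the consensus layer).
#'
#' @param object An `edh_recommendation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edh_recommendation <- function(object, ...) {
  x <- dplyr::mutate(object, edh_index = factor(
    .data$edh_index, levels = c("hc", "dc", "cdhc", "consensus"),
    labels = c("HC", "DC", "CDHC", "Consensus")
  ))
  ggplot2::ggplot(x, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data$recommendation)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$edh_index)) +
    ggplot2::scale_fill_manual(values = c(none = "grey85", NT = "#1b9e77",
                                          CT = "#d95f02")) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Practice",
                  title = "Environment-specific tillage recommendation")
}

#' Plot regional driver contributions
#'
#' Area-weighted mean contribution of each driver by year, faceted by
#' response variable.
#'
#' @param object An `edh_attribution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edh_attribution <- function(object, ...) {
  totals <- attribution_totals(object)
  ggplot2::ggplot(totals, ggplot2::aes(.data$year, .data$area_weighted_mean,
                                       colour = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Area-weighted mean contribution",
                  colour = "Driver",
                  title = "Factorial driver attribution")
}
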