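#' Plot a lead--lag composite
#'
#' One panel per variable, mean anomaly (or summed burned area) against lag
#' around the day of maximum PPA strength.
#'
#' @param object A `ppa_composite` from [leadlag_composite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppa_composite <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::facet_wrap(~.data$variable, scales = "free_y") +
    ggplot2::labs(x = "lag (days) around maximum PPA strength",
                  y = "composite value") +
    ggplot2::theme_minimal()
}

#' Plot an event catalog timeline
#'
#' @param object A `ppa_events` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppa_events <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end,
      y = .data$event_id, yend = .data$event_id,
      linewidth = .data$max_area_km2
    ), colour = "#1b9e77") +
    ggplot2::scale_linewidth(range = c(0.5, 3), name = "max area (km²)") +
    ggplot2::labs(x = NULL, y = "event") +
    ggplot2::theme_minimal()
}

#' Map of cell-level odds ratios for one month
#'
#' @param or_table A `ppa_or` tibble.
#' @param month Calendar month to map (default: all months facetted).
#' @param cap Colour-scale cap; ORs above it are clipped for display.
#' @return A ggplot object.
#' @export
plot_or_map <- function(or_table, month = NULL, cap = 15) {
  df <- tidy(or_table)
  if (!is.null(month)) df <- df[df$month %in% month, ]
  df$or_capped <- pmin(df$or, cap)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                        fill = .data$or_capped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "OR", na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
  if (is.null(month)) p <- p + ggplot2::facet_wrap(~.data$month)
  p
}

#' Map of the average monthly percentage of PPA days
#'
#' @param pct Tibble from [ppa_day_mask()]'s `pct_ppa_days`.
#' @return A ggplot object facetted by month.
#' @export
plot_ppa_days <- function(pct) {
  ggplot2::ggplot(pct, ggplot2::aes(.data$lon, .data$lat, fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% PPA days", option = "B") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~.data$month) +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
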