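#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy and glance methods for event catalogs
#'
#' `tidy()` returns the per-event catalog; `glance()` a one-row summary of
#' the detection run (event count, events per season, mean duration, mean
#' maximum area).
#'
#' @param x A `ppa_events` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ppa_events <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ppa_events")
  out
}

#' @rdname tidy.ppa_events
#' @export
glance.ppa_events <- function(x, ...) {
  n_seasons <- length(unique(season_index(attr(x, "dates"))))
  tibble::tibble(
    n_events = nrow(x),
    events_per_season = nrow(x) / n_seasons,
    mean_duration_days = mean(x$duration_days),
    mean_max_area_km2 = mean(x$max_area_km2),
    mean_max_strength = mean(x$max_strength)
  )
}

#' Tidy and glance methods for odds-ratio tables
#'
#' `tidy()` returns the per-cell-month table; `glance()` the pooled
#' corrected OR, the mean cell-level OR, the share of cell-months with
#' OR > 1, and the number of valid cell-months.
#'
#' @param x A `ppa_or` tibble from [odds_ratio()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ppa_or <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ppa_or")
  out
}

#' @rdname tidy.ppa_or
#' @export
glance.ppa_or <- function(x, ...) {
  valid <- x[!x$insufficient_data, ]
  tibble::tibble(
    pooled_or = pooled_odds_ratio(x, attr(x, "correction") %||% 2),
    mean_or = mean(valid$or),
    median_or = stats::median(valid$or),
    share_gt1 = mean(valid$or > 1),
    n_valid = nrow(valid),
    n_insufficient = sum(x$insufficient_data)
  )
}
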