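#' Day of maximum PPA strength
#'
#' @param events A `ppa_events` object.
#' @return Vector of dates, one per event; ties go to the earliest day.
#' @export
max_strength_day <- function(events) {
  events$max_strength_date
}

#' Lead--lag composite of surface anomalies around maximum PPA strength
#'
#' For each event the footprint is frozen at the member cells on the
#' max-strength day; each anomaly variable is spatially averaged over that
#' footprint at every lag in `-window .. +window` days around the
#' max-strength day. The composite is the unweighted mean across events per
#' lag; burned area is summed across event footprints. Lags falling outside
#' an event's season are dropped for that event, and contributing-event
#' counts per lag are reported. Event strength itself is composited too
#' (zero on days the tracked object does not exist).
#'
#' @param events A `ppa_events` from [label_events()].
#' @param anomalies Named list of anomaly [grid_field()]s (e.g. temp, vpd,
#'   precip, wind, fire-weather indices).
#' @param burned_area Optional [grid_field()] of daily burned hectares.
#' @param window Half-width of the lag window, days (default 15).
#' @return A `ppa_composite` tibble: `lag`, `variable`, `value`, `n_events`.
#'   Burned area appears as variable `"burned_area"` (sum), strength as
#'   `"strength"`.
#' @export
leadlag_composite <- function(events, anomalies, burned_area = NULL,
                              window = 15) {
  detail <- attr(events, "detail")
  if (length(detail) == 0) stop("no events to composite", call. = FALSE)
  dates <- attr(events, "dates")
  grid <- attr(events, "grid")
  seas <- season_index(dates)
  lags <- -window:window
  anom_mats <- purrr::map(anomalies, ~flatten_field(.x$values))
  ba_mat <- if (!is.null(burned_area)) flatten_field(burned_area$values)

  rows <- list()
  for (ev in detail) {
    i0 <- ev$day_idx[which.max(ev$strength)]
    footprint <- ev$cells[[which.max(ev$strength)]]
    for (l in lags) {
      t <- i0 + l
      if (t < 1 || t > length(dates) || seas[t] != seas[i0]) next
      vals <- purrr::map_dbl(anom_mats, ~mean(.x[t, footprint], na.rm = TRUE))
      on_ev <- match(t, ev$day_idx)
      strength <- if (!is.na(on_ev)) ev$strength[on_ev] else 0
      ba <- if (!is.null(ba_mat)) sum(ba_mat[t, footprint]) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lag = l, variable = c(names(anom_mats), "strength", "burned_area"),
        value = c(vals, strength, ba)
      )
    }
  }
  comp <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$lag, .data$variable),
    n_events = dplyr::n(),
    value = if (.data$variable[1] == "burned_area") sum(.data$value)
            else mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  comp <- comp[, c("lag", "variable", "value", "n_events")]
  class(comp) <- c("ppa_composite", class(comp))
  comp
}

#' Per-cell-month PPA-effect t-statistics
#'
#' Ordinary-least-squares slope of the anomaly on the binary PPA/non-PPA
#' indicator, standardised by its standard error. For a binary regressor
#' this equals the pooled-variance two-sample t-statistic (PPA minus
#' non-PPA), which is how it is computed; positive values mean larger
#' anomalies on PPA days. Cell-months with fewer than two days in either
#' group, or zero residual variance, carry no t.
#'
#' @param anom An anomaly [grid_field()].
#' @param exposure Logical PPA mask `[day, lat, lon]` with `dates`/`grid`
#'   attributes.
#' @param variable Label for the output (defaults to the field's name).
#' @return Tibble `lat`, `lon`, `month`, `variable`, `t_stat`,
#'   `n_ppa_days`, `n_non_ppa_days`.
#' @export
ppa_effect_tstat <- function(anom, exposure, variable = anom$variable) {
  dates <- attr(exposure, "dates")
  grid <- attr(exposure, "grid")
  mat <- flatten_field(anom$values)
  exf <- matrix(exposure, dim(exposure)[1], prod(dim(exposure)[2:3]))
  mon <- month_of(dates)
  purrr::map_dfr(sort(unique(mon)), function(m) {
    rows <- which(mon == m)
    x <- mat[rows, , drop = FALSE]
    g <- exf[rows, , drop = FALSE]
    g[is.na(x)] <- NA
    n1 <- colSums(g & !is.na(x), na.rm = TRUE)
    n0 <- colSums(!g & !is.na(x), na.rm = TRUE)
    s1 <- colSums(ifelse(g & !is.na(x), x, 0), na.rm = TRUE)
    s0 <- colSums(ifelse(!g & !is.na(x), x, 0), na.rm = TRUE)
    m1 <- s1 / n1
    m0 <- s0 / n0
    ss1 <- colSums(ifelse(g & !is.na(x), sweep(x, 2, m1)^2, 0), na.rm = TRUE)
    ss0 <- colSums(ifelse(!g & !is.na(x), sweep(x, 2, m0)^2, 0), na.rm = TRUE)
    sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
    t_stat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    bad <- n1 < 2 | n0 < 2 | !is.finite(t_stat) | sp2 <= 0
    t_stat[bad] <- NA_real_
    tibble::tibble(
      lat = rep(grid$lat, times = grid$n_lon),
      lon = rep(grid$lon, each = grid$n_lat),
      month = m, variable = variable, t_stat = t_stat,
      n_ppa_days = n1, n_non_ppa_days = n0
    )
  })
}

#' Multi-month average of t-statistics
#'
#' Averages per-cell t-statistics over a set of months (e.g. June--August
#' for a summer map).
#'
#' @param tstats Output of [ppa_effect_tstat()].
#' @param months Months to average over (default `6:8`).
#' @return Tibble `lat`, `lon`, `variable`, `t_stat`.
#' @export
tstat_monthly_mean <- function(tstats, months = 6:8) {
  dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tstats, .data$month %in% months),
      .data$lat, .data$lon, .data$variable
    ),
    t_stat = mean(.data$t_stat, na.rm = TRUE), .groups = "drop"
  )
}

#' Shapiro--Wilk screen of group-mean residuals
#'
#' Automated stand-in for a visual Q--Q normality assessment of the
#' per-cell-month regression residuals (anomaly minus its group mean):
#' samples up to `n_cells` cell-months and reports the Shapiro--Wilk
#' p-value for each. Results are informational and never enforced.
#'
#' @inheritParams ppa_effect_tstat
#' @param n_cells Maximum number of cell-months to screen (default 25).
#' @return Tibble `lat`, `lon`, `month`, `p_value`, `n`.
#' @export
residual_normality_screen <- function(anom, exposure, n_cells = 25) {
  dates <- attr(exposure, "dates")
  grid <- attr(exposure, "grid")
  mat <- flatten_field(anom$values)
  exf <- matrix(exposure, dim(exposure)[1], prod(dim(exposure)[2:3]))
  mon <- month_of(dates)
  combos <- expand.grid(cell = seq_len(ncol(mat)), month = sort(unique(mon)))
  combos <- combos[seq(1, nrow(combos), length.out = min(n_cells, nrow(combos))), ]
  purrr::pmap_dfr(combos, function(cell, month) {
    rows <- which(mon == month)
    x <- mat[rows, cell]
    g <- exf[rows, cell]
    ok <- !is.na(x)
    x <- x[ok]; g <- g[ok]
    if (length(x) < 5 || length(unique(x)) < 4) {
      return(tibble::tibble(lat = numeric(), lon = numeric(),
                            month = integer(), p_value = numeric(),
                            n = integer()))
    }
    resid <- x - ave(x, g)
    p <- tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) NA_real_)
    i <- ((cell - 1) %% grid$n_lat) + 1
    j <- ((cell - 1) %/% grid$n_lat) + 1
    tibble::tibble(lat = grid$lat[i], lon = grid$lon[j], month = month,
                   p_value = p, n = length(x))
  })
}
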