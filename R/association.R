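# lag-dilate an exposure mask in time: exposed at t iff exposed at any day
# in [t - lag, t] within the same season block
dilate_exposure <- function(mask, dates, lag_days) {
  if (lag_days < 0) stop("lag_days must be non-negative", call. = FALSE)
  d <- dim(mask)
  flat <- matrix(mask, d[1], d[2] * d[3])
  out <- flat
  if (lag_days > 0) {
    for (block in split(seq_len(d[1]), season_index(dates))) {
      m <- flat[block, , drop = FALSE]
      acc <- m
      for (k in seq_len(min(lag_days, nrow(m) - 1))) {
        acc[(k + 1):nrow(m), ] <- acc[(k + 1):nrow(m), , drop = FALSE] |
          m[1:(nrow(m) - k), , drop = FALSE]
      }
      out[block, ] <- acc
    }
  }
  array(out, d)
}

#' Classify cell-days into exposure-by-outcome contingency tables
#'
#' A cell-day is exposed when a PPA overlapped the cell on that day or any
#' of the preceding `lag_days` days (day-anchored reading: every day is
#' classified exactly once, so `a + b + c + d` partitions the analysed
#' days). Counts are accumulated per cell per calendar month across years;
#' a day's month is its own calendar month.
#'
#' @param exposure Logical `[day, lat, lon]` PPA mask (with `dates`/`grid`
#'   attributes, as returned by [ppa_day_mask()]).
#' @param outcome Logical `[day, lat, lon]` outcome indicator (fire day or
#'   extreme-fire-weather day).
#' @param lag_days Exposure look-back, days (7 for fires, 0 for FWIx).
#' @return Tibble `lat`, `lon`, `month`, `a`, `b`, `c`, `d`, `n` with
#'   `a` = exposed & outcome, `b` = exposed & no outcome, `c` = unexposed &
#'   outcome, `d` = unexposed & no outcome.
#' @export
classify_days <- function(exposure, outcome, lag_days = 0) {
  dates <- attr(exposure, "dates")
  grid <- attr(exposure, "grid")
  stopifnot(identical(dim(exposure), dim(outcome)))
  ex <- dilate_exposure(exposure, dates, lag_days)
  d <- dim(ex)
  exf <- matrix(ex, d[1], d[2] * d[3])
  ouf <- matrix(outcome, d[1], d[2] * d[3])
  mon <- month_of(dates)
  res <- purrr::map_dfr(sort(unique(mon)), function(m) {
    rows <- which(mon == m)
    e <- exf[rows, , drop = FALSE]
    o <- ouf[rows, , drop = FALSE]
    tibble::tibble(
      lat = rep(grid$lat, times = grid$n_lon),
      lon = rep(grid$lon, each = grid$n_lat),
      month = m,
      a = colSums(e & o),
      b = colSums(e & !o),
      c = colSums(!e & o),
      d = colSums(!e & !o)
    )
  })
  dplyr::mutate(res, n = .data$a + .data$b + .data$c + .data$d)
}

#' @rdname classify_days
#' @param fire_day Logical fire-day indicator from [rasterize_fires()].
#' @export
classify_fire_days <- function(exposure, fire_day, lag_days = 7) {
  classify_days(exposure, fire_day, lag_days = lag_days)
}

#' @rdname classify_days
#' @param fwix Extreme-fire-weather flags from [extreme_flags()] (the
#'   `flags` array); classified at zero lag.
#' @export
classify_fwix_days <- function(exposure, fwix) {
  classify_days(exposure, fwix, lag_days = 0)
}

#' Odds ratio with partial Haldane correction
#'
#' `OR = (a+k)(d+k) / ((b+k)(c+k))` with the correction `k` added to all
#' four cells of every table, which keeps the estimate finite when a table
#' contains zeros; `k = 2` trades a little shrinkage toward 1 for much
#' lower small-sample bias, `k = 0.5` is the classical Haldane--Anscombe
#' correction, `k = 0` is the raw OR. Cell-months with no outcome days at
#' all (`a + c = 0`) are flagged `insufficient_data` and carry no OR.
#'
#' @param tables Tibble from [classify_days()] (columns `a`, `b`, `c`, `d`).
#' @param correction Correction constant `k` (default 2).
#' @return The input tibble with `or` and `insufficient_data` columns
#'   appended (class `ppa_or`).
#' @export
odds_ratio <- function(tables, correction = 2) {
  k <- correction
  out <- dplyr::mutate(
    tibble::as_tibble(tables),
    insufficient_data = (.data$a + .data$c) == 0,
    or = ifelse(.data$insufficient_data, NA_real_,
                (.data$a + k) * (.data$d + k) / ((.data$b + k) * (.data$c + k)))
  )
  attr(out, "correction") <- k
  class(out) <- c("ppa_or", class(out))
  out
}

#' Pool contingency tables and compute one corrected odds ratio
#'
#' Sums `a`, `b`, `c`, `d` over all rows (cells and months) before applying
#' the correction; the estimator used for synthetic-truth recovery checks.
#'
#' @inheritParams odds_ratio
#' @return Single numeric OR.
#' @export
pooled_odds_ratio <- function(tables, correction = 2) {
  k <- correction
  a <- sum(tables$a); b <- sum(tables$b); c <- sum(tables$c); d <- sum(tables$d)
  (a + k) * (d + k) / ((b + k) * (c + k))
}

#' Regional and monthly summary of cell-level odds ratios
#'
#' Unweighted summaries of valid cell-level ORs within region and month,
#' the pooled per-region summary across that region's cell-months, and the
#' overall mean across regional means (the headline figure). Cells with no
#' observed fire across the whole study (never any outcome in any month)
#' can be excluded upstream by filtering the tables.
#'
#' @param or_table A `ppa_or` tibble from [odds_ratio()].
#' @param regions A `ppa_regions` tibble ([region_map()]).
#' @return List with `by_region_month`, `by_region` (mean, median,
#'   quartiles, share of cells with OR > 1, n), and `overall` (mean across
#'   regional means).
#' @export
regional_summary <- function(or_table, regions) {
  joined <- dplyr::inner_join(
    dplyr::filter(or_table, !.data$insufficient_data),
    regions, by = c("lat", "lon")
  )
  summarise_or <- function(df, ...) {
    dplyr::summarise(
      df,
      mean_or = mean(.data$or),
      median_or = stats::median(.data$or),
      q25 = stats::quantile(.data$or, 0.25, names = FALSE),
      q75 = stats::quantile(.data$or, 0.75, names = FALSE),
      share_gt1 = mean(.data$or > 1),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  }
  by_rm <- summarise_or(dplyr::group_by(joined, .data$region, .data$month))
  by_r <- summarise_or(dplyr::group_by(joined, .data$region))
  list(
    by_region_month = by_rm,
    by_region = by_r,
    overall = mean(by_r$mean_or)
  )
}

#' Burned-area attribution to PPA exposure
#'
#' Percentage of total burned area falling on exposed cell-days (PPA
#' overhead that day or within the preceding `lag_days` days), per region
#' and pooled, plus a lag histogram of burned area by days since the most
#' recent PPA day.
#'
#' @param burned_area A [grid_field()] of daily burned hectares
#'   ([rasterize_fires()]).
#' @param exposure Logical PPA mask with `dates`/`grid` attributes.
#' @param lag_days Exposure look-back, days (default 7).
#' @param regions Optional `ppa_regions`; when `NULL` only the pooled row is
#'   returned.
#' @return List with `attribution` (tibble `region`, `ppa_burned_area_ha`,
#'   `total_burned_area_ha`, `percent`) and `lag_histogram` (tibble
#'   `days_since_ppa` 0..lag_days or NA for unexposed, `burned_area_ha`).
#' @export
burned_area_attribution <- function(burned_area, exposure, lag_days = 7,
                                    regions = NULL) {
  dates <- attr(exposure, "dates")
  grid <- attr(exposure, "grid")
  d <- dim(exposure)
  ba <- flatten_field(burned_area$values)
  exf <- matrix(exposure, d[1], d[2] * d[3])

  # days since the most recent PPA day, per season block; Inf = never/too far
  dsp <- matrix(Inf, d[1], d[2] * d[3])
  for (block in split(seq_len(d[1]), season_index(dates))) {
    m <- exf[block, , drop = FALSE]
    run <- matrix(Inf, nrow(m), ncol(m))
    run[1, ][m[1, ]] <- 0
    if (nrow(m) > 1) {
      for (t in 2:nrow(m)) {
        run[t, ] <- ifelse(m[t, ], 0, run[t - 1, ] + 1)
      }
    }
    dsp[block, ] <- run
  }
  exposed <- dsp <= lag_days

  lat_cell <- rep(grid$lat, times = grid$n_lon)
  lon_cell <- rep(grid$lon, each = grid$n_lat)
  per_cell <- tibble::tibble(
    lat = lat_cell, lon = lon_cell,
    ppa_ba = colSums(ba * exposed),
    total_ba = colSums(ba)
  )
  pooled <- tibble::tibble(
    region = "all",
    ppa_burned_area_ha = sum(per_cell$ppa_ba),
    total_burned_area_ha = sum(per_cell$total_ba)
  )
  attribution <- pooled
  if (!is.null(regions)) {
    by_reg <- dplyr::inner_join(per_cell, regions, by = c("lat", "lon"))
    by_reg <- dplyr::summarise(
      dplyr::group_by(by_reg, .data$region),
      ppa_burned_area_ha = sum(.data$ppa_ba),
      total_burned_area_ha = sum(.data$total_ba),
      .groups = "drop"
    )
    attribution <- dplyr::bind_rows(by_reg, pooled)
  }
  attribution <- dplyr::mutate(
    attribution,
    percent = ifelse(.data$total_burned_area_ha > 0,
                     100 * .data$ppa_burned_area_ha / .data$total_burned_area_ha,
                     NA_real_)
  )

  lag_vals <- as.vector(dsp)
  ba_vals <- as.vector(ba)
  sel <- ba_vals > 0
  lag_bin <- ifelse(is.finite(lag_vals[sel]) & lag_vals[sel] <= lag_days,
                    lag_vals[sel], NA_real_)
  lag_hist <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(days_since_ppa = lag_bin,
                                   ba = ba_vals[sel]),
                    .data$days_since_ppa),
    burned_area_ha = sum(.data$ba), .groups = "drop"
  )
  list(attribution = attribution, lag_histogram = lag_hist)
}
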