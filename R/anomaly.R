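#' Daily climatology across years
#'
#' Long-term mean for each calendar day and cell, computed only from days
#' inside the configured season window (the dates present in the field).
#' The climatology is the raw per-calendar-day cross-year mean; day-level
#' noise is later suppressed by the moving mean applied to anomalies.
#'
#' @param field A [grid_field()] spanning at least two years.
#' @return A `ppa_climatology`: list with `caldays` (`"mm-dd"` keys),
#'   `values` array `[calday, lat, lon]`, and `grid`.
#' @export
daily_climatology <- function(field) {
  yrs <- unique(season_index(field$dates))
  if (length(yrs) < 2) {
    stop("climatology needs at least two years (anomalies would be degenerate)",
         call. = FALSE)
  }
  keys <- calday_key(field$dates)
  caldays <- sort(unique(keys))
  mat <- flatten_field(field$values)
  out <- matrix(NA_real_, length(caldays), ncol(mat))
  for (k in seq_along(caldays)) {
    rows <- which(keys == caldays[k])
    if (length(rows) == 1L) {
      out[k, ] <- mat[rows, ]
    } else {
      out[k, ] <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  structure(
    list(caldays = caldays,
         values = array(out, c(length(caldays), field$grid$n_lat, field$grid$n_lon)),
         grid = field$grid, variable = field$variable, units = field$units),
    class = "ppa_climatology"
  )
}

#' Daily anomalies relative to a climatology
#'
#' @param field A [grid_field()].
#' @param clim A `ppa_climatology` from [daily_climatology()] on a matching
#'   grid; every calendar day in `field` must be present in `clim`.
#' @return A [grid_field()] at stage `"raw"`.
#' @export
compute_anomaly <- function(field, clim) {
  stopifnot(inherits(clim, "ppa_climatology"))
  if (!identical(field$grid$lat, clim$grid$lat) ||
      !identical(field$grid$lon, clim$grid$lon)) {
    stop("field and climatology grids differ", call. = FALSE)
  }
  idx <- match(calday_key(field$dates), clim$caldays)
  if (anyNA(idx)) {
    stop("calendar day missing from climatology: ",
         paste(unique(calday_key(field$dates)[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  cm <- flatten_field(clim$values)[idx, , drop = FALSE]
  anom <- flatten_field(field$values) - cm
  grid_field(unflatten_field(anom, field$grid), field$dates, field$grid,
             variable = paste0(field$variable, "_anom"), units = field$units,
             stage = "raw")
}

#' Centred moving-mean smoothing in time
#'
#' Applies an odd-width centred moving mean per cell. At season edges the
#' window shrinks to the available days; windows never cross a season
#' boundary (seasons are the per-year date blocks of the field).
#'
#' @param anom A [grid_field()] at stage `"raw"`.
#' @param window_days Odd window width, days (default 5).
#' @return A [grid_field()] at stage `"smoothed"`.
#' @export
smooth_time <- function(anom, window_days = 5) {
  if (window_days < 1 || window_days %% 2 == 0) {
    stop("window_days must be odd and >= 1", call. = FALSE)
  }
  half <- (window_days - 1L) %/% 2L
  mat <- flatten_field(anom$values)
  out <- matrix(NA_real_, nrow(mat), ncol(mat))
  for (block in split(seq_along(anom$dates), season_index(anom$dates))) {
    m <- mat[block, , drop = FALSE]
    n <- nrow(m)
    filled <- ifelse(is.na(m), 0, m)
    cnt <- 1 - is.na(m)
    cs <- rbind(0, apply(filled, 2, cumsum))
    cc <- rbind(0, apply(cnt, 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sums <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    ns <- cc[hi + 1L, , drop = FALSE] - cc[lo, , drop = FALSE]
    sm <- sums / ns
    sm[ns == 0] <- NA_real_
    out[block, ] <- sm
  }
  grid_field(unflatten_field(out, anom$grid), anom$dates, anom$grid,
             variable = anom$variable, units = anom$units, stage = "smoothed")
}

#' Latitude correction for atmospheric energy dispersion
#'
#' Scales each anomaly by `sin(ref_lat)/sin(lat)` so that equal geostrophic
#' forcing is weighted equally across latitudes (height anomalies of a given
#' circulation strength grow with the Coriolis parameter).
#'
#' @param anom A [grid_field()] at stage `"smoothed"` (or `"raw"`).
#' @param ref_lat Reference latitude, degrees north (default 45).
#' @return A [grid_field()] at stage `"latitude_corrected"`.
#' @export
latitude_correction <- function(anom, ref_lat = 45) {
  if (any(anom$grid$lat <= 0)) {
    stop("latitude correction requires a northern-hemisphere grid (lat > 0)",
         call. = FALSE)
  }
  fac <- sin(ref_lat * pi / 180) / sin(anom$grid$lat * pi / 180)
  vals <- anom$values * rep(fac, each = length(anom$dates))
  grid_field(vals, anom$dates, anom$grid, variable = anom$variable,
             units = anom$units, stage = "latitude_corrected")
}

#' Seasonally varying magnitude threshold
#'
#' For each calendar day, pools the latitude-corrected anomalies in a moving
#' window centred on that day across all years, takes the per-cell standard
#' deviation, and averages over all domain cells to give one scalar
#' threshold per calendar day ("daily varying mean standard deviation").
#' A per-cell variant (no domain averaging) is available via `per_cell`.
#'
#' @param anom A [grid_field()] at stage `"latitude_corrected"` spanning at
#'   least two years.
#' @param window_days Moving-window width, days (default 28; for even widths
#'   the window covers `d - w/2 .. d + w/2 - 1`). Edge windows shrink and
#'   never cross the season boundary.
#' @param multiplier Magnitude multiplier stored with the series (default 1);
#'   detection flags cells with anomaly `>= multiplier * threshold`.
#' @param per_cell If `TRUE`, return per-cell thresholds instead of the
#'   domain-mean scalar.
#' @return A tibble `calday`, `threshold` (class `ppa_threshold`, attribute
#'   `multiplier`), or with additional `lat`, `lon` columns when `per_cell`.
#' @export
seasonal_threshold <- function(anom, window_days = 28, multiplier = 1,
                               per_cell = FALSE) {
  if (!identical(anom$stage, "latitude_corrected")) {
    stop("seasonal_threshold expects latitude-corrected anomalies", call. = FALSE)
  }
  yrs <- unique(season_index(anom$dates))
  if (length(yrs) < 2) stop("threshold needs at least two years", call. = FALSE)
  keys <- calday_key(anom$dates)
  caldays <- sort(unique(keys))
  ncal <- length(caldays)
  if (window_days > ncal) stop("window longer than the season", call. = FALSE)
  # window in day-of-season index space; shrinks at season edges
  lo_off <- -(window_days %/% 2L)
  hi_off <- lo_off + window_days - 1L
  day_pos <- match(keys, caldays)
  mat <- flatten_field(anom$values)
  thr <- numeric(ncal)
  thr_cell <- if (per_cell) matrix(NA_real_, ncal, ncol(mat)) else NULL
  for (d in seq_len(ncal)) {
    win <- max(1L, d + lo_off):min(ncal, d + hi_off)
    rows <- which(day_pos %in% win)
    m <- mat[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    ss <- colSums(sweep(m, 2, mu)^2, na.rm = TRUE)
    sds <- sqrt(ss / pmax(n_ok - 1, 1))
    sds[n_ok < 2] <- NA_real_
    if (per_cell) thr_cell[d, ] <- sds
    thr[d] <- mean(sds, na.rm = TRUE)
  }
  if (per_cell) {
    g <- anom$grid
    out <- tibble::tibble(
      calday = rep(caldays, times = g$n_lat * g$n_lon),
      lat = rep(rep(g$lat, each = ncal), times = g$n_lon),
      lon = rep(g$lon, each = ncal * g$n_lat),
      threshold = as.vector(thr_cell)
    )
  } else {
    out <- tibble::tibble(calday = caldays, threshold = thr)
  }
  attr(out, "multiplier") <- multiplier
  class(out) <- c("ppa_threshold", class(out))
  out
}

#' Anomalies of a set of surface variables
#'
#' Convenience wrapper: per-calendar-day climatology and raw anomaly for
#' each field, with no temporal smoothing and no latitude correction
#' (surface variables enter composites and t-statistics as plain anomalies).
#'
#' @param fields Named list of [grid_field()]s.
#' @return Named list of anomaly [grid_field()]s (stage `"raw"`).
#' @export
surface_anomalies <- function(fields) {
  purrr::map(fields, function(f) compute_anomaly(f, daily_climatology(f)))
}
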