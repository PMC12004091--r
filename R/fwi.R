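#' Vapour pressure deficit
#'
#' Saturation vapour pressure follows the Magnus-type formula
#' `e_s(T) = 6.112 exp(17.67 T / (T + 243.5))` hPa; VPD is
#' `e_s(T) * (1 - RH/100)`.
#'
#' @param temp Air temperature, degrees C.
#' @param rh Relative humidity, percent (0--100).
#' @return VPD in hPa, non-negative.
#' @export
vpd <- function(temp, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("rh must lie in [0, 100]", call. = FALSE)
  }
  es <- 6.112 * exp(17.67 * temp / (temp + 243.5))
  es * (1 - rh / 100)
}

#' Hot--dry--windy index
#'
#' Product of the maximum VPD and the maximum wind speed over the supplied
#' near-surface levels (the lowest ~50 hPa layer); the maxima may come from
#' different levels.
#'
#' @param vpd_levels Numeric vector or `[level, n]` matrix of VPD, hPa.
#' @param wind_levels Same shape, wind speed in m/s.
#' @return HDWI in hPa m/s.
#' @export
hdwi <- function(vpd_levels, wind_levels) {
  if (length(vpd_levels) == 0 || length(wind_levels) == 0) {
    stop("hdwi needs at least one level", call. = FALSE)
  }
  if (is.matrix(vpd_levels)) {
    apply(vpd_levels, 2, max) * apply(wind_levels, 2, max)
  } else {
    max(vpd_levels) * max(wind_levels)
  }
}

# CFWIS day-length factors, standard monthly tables (46N reference)
DMC_DAY_LENGTH <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
DC_DAY_LENGTH  <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

#' Default CFWIS start-up state
#'
#' Standard season start-up moisture codes: FFMC 85, DMC 6, DC 15.
#'
#' @param n Number of cells (state vectors are recycled to length `n`).
#' @return List with `ffmc`, `dmc`, `dc` numeric vectors.
#' @export
fwi_init_state <- function(n = 1) {
  list(ffmc = rep(85, n), dmc = rep(6, n), dc = rep(15, n))
}

#' One daily step of the Canadian Fire Weather Index System
#'
#' Advances the three moisture codes from the previous day's values using
#' noon weather, then computes the three behaviour indices. Equations and
#' constants follow the published standard system definition (Van Wagner's
#' structure: rain then drying/wetting phases for FFMC; rain then
#' temperature/humidity log-drying for DMC; rain then potential
#' evapotranspiration for DC; ISI from FFMC and wind; BUI from DMC and DC;
#' FWI from ISI and BUI). All arguments are vectorized over cells.
#'
#' @param state List with `ffmc`, `dmc`, `dc` (previous day).
#' @param temp Noon temperature, degrees C.
#' @param rh Noon relative humidity, percent.
#' @param wind Noon 10 m wind speed, km/h.
#' @param prec 24 h accumulated precipitation, mm.
#' @param month Calendar month 1--12 (day-length factors).
#' @return List with updated `state` plus `isi`, `bui`, `fwi`.
#' @export
cfwis_step <- function(state, temp, rh, wind, prec, month) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) stop("rh outside [0,100]", call. = FALSE)
  if (any(wind < 0, na.rm = TRUE)) stop("negative wind", call. = FALSE)
  if (any(prec < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  rh <- pmin(rh, 100)

  ## --- FFMC ---
  f0 <- state$ffmc
  mo <- 147.2 * (101 - f0) / (59.5 + f0)
  rainy <- prec > 0.5
  if (any(rainy)) {
    rf <- prec[rainy] - 0.5
    mr <- mo[rainy] +
      42.5 * rf * exp(-100 / (251 - mo[rainy])) * (1 - exp(-6.93 / rf))
    wet <- mo[rainy] > 150
    mr[wet] <- mr[wet] +
      0.0015 * (mo[rainy][wet] - 150)^2 * sqrt(rf[wet])
    mr <- pmin(mr, 250)
    mo[rainy] <- mr
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  m <- mo
  drying <- mo > ed
  if (any(drying)) {
    ko <- 0.424 * (1 - (rh[drying] / 100)^1.7) +
      0.0694 * sqrt(wind[drying]) * (1 - (rh[drying] / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * temp[drying])
    m[drying] <- ed[drying] + (mo[drying] - ed[drying]) * 10^(-kd)
  }
  ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  wetting <- !drying & mo < ew
  if (any(wetting)) {
    k1 <- 0.424 * (1 - ((100 - rh[wetting]) / 100)^1.7) +
      0.0694 * sqrt(wind[wetting]) * (1 - ((100 - rh[wetting]) / 100)^8)
    kw <- k1 * 0.581 * exp(0.0365 * temp[wetting])
    m[wetting] <- ew[wetting] - (ew[wetting] - mo[wetting]) * 10^(-kw)
  }
  ffmc <- 59.5 * (250 - m) / (147.2 + m)
  ffmc <- pmin(pmax(ffmc, 0), 101)

  ## --- DMC ---
  p0 <- state$dmc
  if (any(prec > 1.5)) {
    sel <- prec > 1.5
    re <- 0.92 * prec[sel] - 1.27
    mo_d <- 20 + 280 / exp(0.023 * p0[sel])
    b <- ifelse(p0[sel] <= 33, 100 / (0.5 + 0.3 * p0[sel]),
                ifelse(p0[sel] <= 65, 14 - 1.3 * log(p0[sel]),
                       6.2 * log(p0[sel]) - 17.2))
    mr_d <- mo_d + 1000 * re / (48.77 + b * re)
    pr <- 43.43 * (5.6348 - log(mr_d - 20))
    p0[sel] <- pmax(pr, 0)
  }
  t_dmc <- pmax(temp, -1.1)
  k_dmc <- 1.894 * (t_dmc + 1.1) * (100 - rh) * DMC_DAY_LENGTH[month] * 1e-6
  dmc <- p0 + 100 * k_dmc

  ## --- DC ---
  d0 <- state$dc
  if (any(prec > 2.8)) {
    sel <- prec > 2.8
    rd <- 0.83 * prec[sel] - 1.27
    q0 <- 800 * exp(-d0[sel] / 400)
    qr <- q0 + 3.937 * rd
    dr <- 400 * log(800 / qr)
    d0[sel] <- pmax(dr, 0)
  }
  t_dc <- pmax(temp, -2.8)
  v <- pmax(0.36 * (t_dc + 2.8) + DC_DAY_LENGTH[month], 0)
  dc <- d0 + 0.5 * v

  ## --- ISI ---
  fw <- exp(0.05039 * wind)
  m_isi <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  ff <- 91.9 * exp(-0.1386 * m_isi) * (1 + m_isi^5.31 / 4.93e7)
  isi <- 0.208 * fw * ff

  ## --- BUI ---
  bui <- ifelse(
    dmc <= 0.4 * dc,
    ifelse(dmc + 0.4 * dc > 0, 0.8 * dmc * dc / (dmc + 0.4 * dc), 0),
    dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) * (0.92 + (0.0114 * dmc)^1.7)
  )
  bui <- pmax(bui, 0)

  ## --- FWI ---
  fd <- ifelse(bui <= 80, 0.626 * bui^0.809 + 2,
               1000 / (25 + 108.64 * exp(-0.023 * bui)))
  b_int <- 0.1 * isi * fd
  fwi <- ifelse(b_int > 1, exp(2.72 * (0.434 * log(b_int))^0.647), b_int)

  list(state = list(ffmc = ffmc, dmc = dmc, dc = dc),
       isi = isi, bui = bui, fwi = fwi)
}

#' Run the CFWIS over a daily weather table
#'
#' Folds [cfwis_step()] over a contiguous daily weather series for one
#' location, resetting the moisture codes to `init` at each season (year
#' block) start: no overwintering of the drought code.
#'
#' @param wx Data frame with columns `date`, `temp` (C), `rh` (%),
#'   `wind` (km/h), `prec` (mm).
#' @param init Start-up state from [fwi_init_state()].
#' @return Tibble: `date`, `ffmc`, `dmc`, `dc`, `isi`, `bui`, `fwi`, `vpd`.
#' @export
cfwis <- function(wx, init = fwi_init_state(1)) {
  dates <- as.Date(wx$date)
  n <- length(dates)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("ffmc", "dmc", "dc", "isi", "bui", "fwi")))
  seas <- season_index(dates)
  state <- init
  for (t in seq_len(n)) {
    if (t == 1 || seas[t] != seas[t - 1]) {
      state <- init
    } else if (as.integer(dates[t] - dates[t - 1]) != 1L) {
      stop("gap in daily weather series at ", dates[t], call. = FALSE)
    }
    st <- cfwis_step(state, wx$temp[t], wx$rh[t], wx$wind[t], wx$prec[t],
                     month_of(dates[t]))
    state <- st$state
    out[t, ] <- c(state$ffmc, state$dmc, state$dc, st$isi, st$bui, st$fwi)
  }
  dplyr::bind_cols(tibble::tibble(date = dates), tibble::as_tibble(out),
                   tibble::tibble(vpd = vpd(wx$temp, wx$rh)))
}

#' Run the CFWIS over gridded weather fields
#'
#' Same fold as [cfwis()] but vectorized over all grid cells at once.
#'
#' @param weather Named list of [grid_field()]s: `temp` (C), `rh` (%),
#'   `wind` (km/h), `prec` (mm), on a common grid and calendar.
#' @param init Start-up codes applied at each season start.
#' @return Named list of [grid_field()]s: `ffmc`, `dmc`, `dc`, `isi`,
#'   `bui`, `fwi`, `vpd`.
#' @export
cfwis_run <- function(weather, init = NULL) {
  tm <- flatten_field(weather$temp$values)
  rh <- flatten_field(weather$rh$values)
  wd <- flatten_field(weather$wind$values)
  pr <- flatten_field(weather$prec$values)
  dates <- weather$temp$dates
  grid <- weather$temp$grid
  n_cell <- ncol(tm)
  if (is.null(init)) init <- fwi_init_state(n_cell)
  seas <- season_index(dates)
  months <- month_of(dates)
  out <- purrr::map(c("ffmc", "dmc", "dc", "isi", "bui", "fwi"),
                    ~matrix(NA_real_, nrow(tm), n_cell))
  names(out) <- c("ffmc", "dmc", "dc", "isi", "bui", "fwi")
  state <- init
  for (t in seq_len(nrow(tm))) {
    if (t == 1 || seas[t] != seas[t - 1]) {
      state <- init
    } else if (as.integer(dates[t] - dates[t - 1]) != 1L) {
      stop("gap in daily weather series at ", dates[t], call. = FALSE)
    }
    st <- cfwis_step(state, tm[t, ], rh[t, ], wd[t, ], pr[t, ], months[t])
    state <- st$state
    out$ffmc[t, ] <- state$ffmc
    out$dmc[t, ] <- state$dmc
    out$dc[t, ] <- state$dc
    out$isi[t, ] <- st$isi
    out$bui[t, ] <- st$bui
    out$fwi[t, ] <- st$fwi
  }
  res <- purrr::imap(out, function(m, nm) {
    grid_field(unflatten_field(m, grid), dates, grid, variable = nm)
  })
  res$vpd <- grid_field(
    unflatten_field(vpd(tm, rh), grid), dates, grid,
    variable = "vpd", units = "hPa"
  )
  res
}

#' Extreme fire-weather flags (FWIx)
#'
#' The extreme threshold is the 95th percentile (linear interpolation
#' between order statistics) of a cell's FWI values pooled over a calendar
#' month across all years; a day is extreme when its FWI is strictly
#' greater than the threshold.
#'
#' @param fwi A [grid_field()] of daily FWI.
#' @param q Percentile in (0, 1), default 0.95.
#' @param min_pool Pool size below which a warning is emitted (default 20).
#' @return List with `thresholds` (tibble `lat`, `lon`, `month`,
#'   `fwix_threshold`) and `flags` (logical `[day, lat, lon]`).
#' @export
extreme_flags <- function(fwi, q = 0.95, min_pool = 20) {
  mat <- flatten_field(fwi$values)
  mon <- month_of(fwi$dates)
  g <- fwi$grid
  months <- sort(unique(mon))
  flags <- matrix(FALSE, nrow(mat), ncol(mat))
  thr_rows <- list()
  warn_small <- FALSE
  for (m in months) {
    rows <- which(mon == m)
    pool <- mat[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(pool))
    if (any(n_ok > 0 & n_ok < min_pool)) warn_small <- TRUE
    thr <- apply(pool, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      stats::quantile(x, q, type = 7, names = FALSE)
    })
    flags[rows, ] <- sweep(pool, 2, thr, `>`) & !is.na(pool)
    thr_rows[[length(thr_rows) + 1L]] <- tibble::tibble(
      lat = rep(g$lat, times = g$n_lon),
      lon = rep(g$lon, each = g$n_lat),
      month = m, fwix_threshold = thr
    )
  }
  if (warn_small) {
    warning("some cell-month pools have fewer than ", min_pool, " FWI values",
            call. = FALSE)
  }
  flags[is.na(flags)] <- FALSE
  out_flags <- array(flags, c(nrow(mat), g$n_lat, g$n_lon))
  attr(out_flags, "dates") <- fwi$dates
  attr(out_flags, "grid") <- g
  list(thresholds = dplyr::bind_rows(thr_rows), flags = out_flags)
}
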