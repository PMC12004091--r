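#' Synthetic-world configuration
#'
#' Defines the study conditions for the synthetic generator: grid and
#' season geometry, background-field statistics, injected-event properties,
#' surface--event couplings, and the fire model with a known true exposure
#' odds ratio. Defaults are the desk-scale study conditions used throughout
#' the package's tests and documentation.
#'
#' @param lat,lon Grid cell centres (degrees).
#' @param years Calendar years simulated (each contributes one
#'   March--October season). At least two are needed for climatologies.
#' @param season_months First and last month of the season window.
#' @param rho Day-to-day AR(1) coefficient of the background field in
#'   `[0, 1)`; 0 gives temporally white noise.
#' @param sigma_z Marginal standard deviation of the background Z500 field,
#'   gpm.
#' @param smooth_len Spatial Gaussian smoothing length of the background
#'   noise, in cells.
#' @param events_per_season Injected persistent events per season.
#' @param amp_range Peak event amplitude as a multiple of the realized
#'   seasonal threshold (drawn uniformly).
#' @param radius_range Gaussian bump scale, cells (drawn uniformly).
#' @param duration_range Event duration, days (drawn uniformly, integer).
#' @param drift Event centre drift, cells/day (random direction).
#' @param delta_t Warm anomaly on event days, degrees C.
#' @param delta_rh Relative-humidity depression on event days, percent.
#' @param wind_factor Multiplicative wind reduction on event days.
#' @param precip_suppression Fractional reduction of precipitation
#'   occurrence probability on event days, reached after the drying ramp.
#' @param drying_ramp_days Days into an event over which the precipitation
#'   suppression ramps up to its full value; drought builds progressively
#'   under a persistent ridge, so the precipitation minimum lags peak event
#'   strength.
#' @param p0 Baseline daily fire probability per cell.
#' @param or_true True exposure odds multiplier for fires.
#' @param fire_lag_days Exposure look-back used by the fire model.
#' @param fire_size_median_ha,fire_size_sdlog Log-normal burned-area sizes.
#' @param seed Integer seed; every generator stage derives its stream from
#'   it, so a fixed seed gives bit-identical worlds.
#' @return A `synth_config` list.
#' @export
synth_config <- function(lat = 40:55, lon = 0:15, years = 2001:2003,
                         season_months = c(3, 10),
                         rho = 0.8, sigma_z = 80, smooth_len = 2,
                         events_per_season = 2, amp_range = c(1.5, 3),
                         radius_range = c(2.5, 3.5),
                         duration_range = c(8, 12), drift = 0.25,
                         delta_t = 4, delta_rh = 15, wind_factor = 0.7,
                         precip_suppression = 0.5, drying_ramp_days = 10,
                         p0 = 0.01, or_true = 3, fire_lag_days = 7,
                         fire_size_median_ha = 100, fire_size_sdlog = 1,
                         seed = 1) {
  stopifnot(rho >= 0, rho < 1, p0 >= 0, p0 < 1,
            or_true > 0, all(amp_range > 1), length(years) >= 1)
  structure(
    list(lat = lat, lon = lon, years = years, season_months = season_months,
         rho = rho, sigma_z = sigma_z, smooth_len = smooth_len,
         events_per_season = events_per_season, amp_range = amp_range,
         radius_range = radius_range, duration_range = duration_range,
         drift = drift, delta_t = delta_t, delta_rh = delta_rh,
         wind_factor = wind_factor, precip_suppression = precip_suppression,
         drying_ramp_days = drying_ramp_days,
         p0 = p0, or_true = or_true, fire_lag_days = fire_lag_days,
         fire_size_median_ha = fire_size_median_ha,
         fire_size_sdlog = fire_size_sdlog, seed = seed),
    class = "synth_config"
  )
}

# all season dates for the configured years
season_dates <- function(config) {
  do.call(c, lapply(config$years, function(y) {
    seq(as.Date(sprintf("%d-%02d-01", y, config$season_months[1])),
        last_day_of_month(y, config$season_months[2]), by = "day")
  }))
}

last_day_of_month <- function(year, month) {
  first_next <- if (month == 12) as.Date(sprintf("%d-01-01", year + 1))
                else as.Date(sprintf("%d-%02d-01", year, month + 1))
  first_next - 1
}

# row-normalized Gaussian smoothing operator over grid cells (unit marginal
# variance for white-noise input); distances in cell-index units
smoothing_operator <- function(n_lat, n_lon, len) {
  if (len <= 0) return(diag(n_lat * n_lon))  # fully i.i.d. background
  ii <- rep(seq_len(n_lat), times = n_lon)
  jj <- rep(seq_len(n_lon), each = n_lat)
  d2 <- outer(ii, ii, `-`)^2 + outer(jj, jj, `-`)^2
  w <- exp(-d2 / (2 * len^2))
  w / sqrt(rowSums(w^2))
}

# smooth seasonal-mean Z500 surface (latitude gradient + seasonal cycle)
seasonal_surface <- function(dates, grid) {
  sday <- as.integer(format(dates, "%j"))
  cyc <- 80 * sin(pi * (sday - min(sday)) / (max(sday) - min(sday) + 1))
  latg <- -4 * (grid$lat - mean(grid$lat))
  outer(cyc, rep(latg, times = grid$n_lon), `+`) + 5600
}

#' Generate a synthetic Z500 field with injected persistent events
#'
#' The background is an AR(1)-in-time process of spatially smoothed
#' Gaussian noise with unit marginal variance, scaled to `sigma_z` and added
#' to a smooth seasonal-mean surface. The realized seasonal threshold of the
#' pure background is computed by running the anomaly pipeline (climatology,
#' 5-day smoothing, latitude correction, 28-day threshold window), and
#' events are then injected as spatial Gaussian bumps whose *processed*
#' peak amplitude equals the configured multiple of that threshold: the raw
#' amplitude is divided by the latitude-correction factor at the bump
#' centre and inflated by `n_years / (n_years - 1)` to offset the share the
#' climatology absorbs. Bumps persist for the drawn duration with optional
#' slow drift. The truth footprint of an event-day is the set of cells
#' whose expected processed amplitude still exceeds the threshold.
#'
#' @param config A [synth_config()].
#' @return List with `field` (the [grid_field()] of Z500), and `truth`
#'   (class `synthetic_truth`): `catalog` tibble (one row per event:
#'   `event`, `year`, `start`, `end`, `duration_days`, `amplitude_mult`,
#'   `radius_cells`, `center_lat`, `center_lon`), `mask` (logical truth
#'   exposure array), `threshold_ref` (gpm), and the coupling/fire
#'   parameters.
#' @export
gen_z500 <- function(config) {
  set.seed(config$seed)
  grid <- ppa_grid(config$lat, config$lon)
  dates <- season_dates(config)
  nt <- length(dates)
  n_cell <- grid$n_lat * grid$n_lon
  W <- smoothing_operator(grid$n_lat, grid$n_lon, config$smooth_len)

  bg <- matrix(0, nt, n_cell)
  for (block in split(seq_len(nt), season_index(dates))) {
    n <- length(block)
    eps <- W %*% matrix(stats::rnorm(n_cell * n), n_cell, n)
    a <- matrix(0, n_cell, n)
    a[, 1] <- eps[, 1]
    if (n > 1) {
      sc <- sqrt(1 - config$rho^2)
      for (t in 2:n) a[, t] <- config$rho * a[, t - 1] + sc * eps[, t]
    }
    bg[block, ] <- t(a) * config$sigma_z
  }
  # Z500 anomaly variance grows with the Coriolis parameter; scale the
  # background s.d. by sin(lat)/sin(45) so the latitude correction
  # equalizes it, as it does for the real atmosphere
  lat_sd <- sin(grid$lat * pi / 180) / sin(45 * pi / 180)
  bg <- bg * rep(rep(lat_sd, times = grid$n_lon), each = nt)
  surf <- seasonal_surface(dates, grid)
  base_vals <- unflatten_field(bg + surf, grid)
  base_field <- grid_field(base_vals, dates, grid, variable = "z500", units = "gpm")

  # realized threshold of the pure background (no RNG involved); thresholds
  # derive from the unsmoothed latitude-corrected anomaly
  thr <- seasonal_threshold(
    latitude_correction(
      compute_anomaly(base_field, daily_climatology(base_field))),
    28)
  thr_ref <- mean(thr$threshold)

  # inject events
  n_years <- length(config$years)
  lat_fac <- sin(45 * pi / 180) / sin(grid$lat * pi / 180)
  ii <- rep(seq_len(grid$n_lat), times = grid$n_lon)
  jj <- rep(seq_len(grid$n_lon), each = grid$n_lat)
  vals <- flatten_field(base_vals)
  mask <- matrix(FALSE, nt, n_cell)
  cat_rows <- list()
  ev_detail <- list()
  # overlap rejection lives in (day-of-season, cell) space across ALL years:
  # events colliding in calendar days and location would corrupt each
  # other's anomalies through the shared climatology
  season_len <- max(table(season_index(dates)))
  taken <- matrix(FALSE, season_len, n_cell)
  ev_id <- 0L
  for (yr_block in split(seq_len(nt), season_index(dates))) {
    n <- length(yr_block)
    for (k in seq_len(config$events_per_season)) {
      placed <- FALSE
      for (try in 1:50) {
        m_amp <- stats::runif(1, config$amp_range[1], config$amp_range[2])
        s <- stats::runif(1, config$radius_range[1], config$radius_range[2])
        dur <- sample(config$duration_range[1]:config$duration_range[2], 1)
        r_eff <- s * sqrt(2 * log(m_amp))
        margin <- ceiling(r_eff) + 1
        if (2 * margin >= min(grid$n_lat, grid$n_lon) || dur + 12 > n) break
        i0 <- stats::runif(1, margin + 1, grid$n_lat - margin)
        j0 <- stats::runif(1, margin + 1, grid$n_lon - margin)
        t0 <- sample(6:(n - dur - 6), 1)
        ang <- stats::runif(1, 0, 2 * pi)
        days <- yr_block[t0:(t0 + dur - 1)]
        # candidate footprint over all days (for overlap rejection)
        centers <- cbind(i0 + config$drift * cos(ang) * (seq_len(dur) - 1),
                         j0 + config$drift * sin(ang) * (seq_len(dur) - 1))
        fp <- lapply(seq_len(dur), function(q) {
          which((ii - centers[q, 1])^2 + (jj - centers[q, 2])^2 <= r_eff^2)
        })
        pad_lo <- max(1, t0 - 3); pad_hi <- min(n, t0 + dur + 2)
        clash <- any(vapply(seq_len(dur), function(q) {
          any(taken[pad_lo:pad_hi, fp[[q]]])
        }, TRUE))
        if (clash || any(vapply(fp, length, 0L) == 0)) next
        # inject
        ctr_lat_idx <- round(i0)
        amp_raw <- m_amp * thr_ref / lat_fac[ctr_lat_idx] *
          n_years / max(n_years - 1, 1)
        # core footprint: expected processed amplitude at least midway
        # between the threshold and the peak (half-prominence region)
        r_core <- s * sqrt(2 * log(2 * m_amp / (1 + m_amp)))
        core <- lapply(seq_len(dur), function(q) {
          which((ii - centers[q, 1])^2 + (jj - centers[q, 2])^2 <= r_core^2)
        })
        for (q in seq_len(dur)) {
          d2 <- (ii - centers[q, 1])^2 + (jj - centers[q, 2])^2
          vals[days[q], ] <- vals[days[q], ] + amp_raw * exp(-d2 / (2 * s^2))
          mask[days[q], fp[[q]]] <- TRUE
          taken[t0 + q - 1L, fp[[q]]] <- TRUE
        }
        ev_id <- ev_id + 1L
        ev_detail[[ev_id]] <- list(day_idx = days, cells = fp, core = core)
        cat_rows[[ev_id]] <- tibble::tibble(
          event = ev_id, year = season_index(dates)[days[1]],
          start = dates[days[1]], end = dates[days[dur]],
          duration_days = dur, amplitude_mult = m_amp, radius_cells = s,
          center_lat = grid$lat[ctr_lat_idx], center_lon = grid$lon[round(j0)]
        )
        placed <- TRUE
        break
      }
      if (!placed) next
    }
  }
  mask_arr <- array(mask, c(nt, grid$n_lat, grid$n_lon))
  attr(mask_arr, "dates") <- dates
  attr(mask_arr, "grid") <- grid
  truth <- structure(
    list(catalog = if (ev_id > 0) dplyr::bind_rows(cat_rows) else tibble::tibble(),
         detail = ev_detail, mask = mask_arr, threshold_ref = thr_ref,
         grid = grid, dates = dates, config = config),
    class = "synthetic_truth"
  )
  list(field = grid_field(unflatten_field(vals, grid), dates, grid,
                          variable = "z500", units = "gpm"),
       truth = truth)
}

#' Generate surface weather coupled to the injected events
#'
#' Independent daily weather noise with a seasonal temperature cycle,
#' modified on truth event cell-days: temperature is shifted by `+delta_t`,
#' relative humidity by `-delta_rh` (clipped to `[0, 100]`), wind is
#' multiplied by `wind_factor`, and precipitation occurrence probability is
#' reduced by `precip_suppression`. Also returns two near-surface levels of
#' (VPD, wind) for the hot--dry--windy index.
#'
#' @param truth A `synthetic_truth` from [gen_z500()].
#' @param config The same [synth_config()].
#' @return Named list of [grid_field()]s: `temp` (C), `rh` (%), `wind`
#'   (km/h), `prec` (mm), plus `hdwi_levels`: list of two levels, each with
#'   `vpd` (hPa) and `wind_ms` (m/s) fields.
#' @export
gen_surface <- function(truth, config) {
  set.seed(config$seed + 1L)
  grid <- truth$grid
  dates <- truth$dates
  nt <- length(dates)
  n_cell <- grid$n_lat * grid$n_lon
  on_ev <- matrix(truth$mask, nt, n_cell)
  sday <- as.integer(format(dates, "%j"))
  cyc <- 12 * sin(pi * (sday - min(sday)) / (max(sday) - min(sday) + 1))

  temp <- matrix(stats::rnorm(nt * n_cell, 0, 2), nt, n_cell) + 10 + cyc
  temp <- temp + config$delta_t * on_ev
  rh <- matrix(stats::rnorm(nt * n_cell, 65, 12), nt, n_cell)
  rh <- rh - config$delta_rh * on_ev
  rh <- pmin(pmax(rh, 0), 100)
  wind <- matrix(stats::rgamma(nt * n_cell, shape = 2, scale = 7.5), nt, n_cell)
  wind <- wind * ifelse(on_ev, config$wind_factor, 1)
  # progressive drying: suppression ramps up with days into the event
  pos <- matrix(0, nt, n_cell)
  for (block in split(seq_len(nt), season_index(dates))) {
    m <- on_ev[block, , drop = FALSE]
    run <- matrix(0, nrow(m), ncol(m))
    run[1, ] <- as.numeric(m[1, ])
    if (nrow(m) > 1) {
      for (t in 2:nrow(m)) run[t, ] <- ifelse(m[t, ], run[t - 1, ] + 1, 0)
    }
    pos[block, ] <- run
  }
  supp <- config$precip_suppression * pmin(1, pos / config$drying_ramp_days)
  p_wet <- 0.3 * (1 - supp)
  wet <- matrix(stats::runif(nt * n_cell), nt, n_cell) < p_wet
  amount <- matrix(stats::rgamma(nt * n_cell, shape = 0.7, scale = 8), nt, n_cell)
  prec <- ifelse(wet, amount, 0)

  f <- function(m, nm, un) grid_field(unflatten_field(m, grid), dates, grid,
                                      variable = nm, units = un)
  vpd_sfc <- vpd(temp, rh)
  wind_ms <- wind / 3.6
  # a slightly drier, windier layer just above the surface
  vpd_up <- vpd_sfc * matrix(stats::runif(nt * n_cell, 1.0, 1.15), nt, n_cell)
  wind_up <- wind_ms * matrix(stats::runif(nt * n_cell, 1.0, 1.25), nt, n_cell)
  list(
    temp = f(temp, "temp", "degC"),
    rh = f(rh, "rh", "%"),
    wind = f(wind, "wind", "km/h"),
    prec = f(prec, "prec", "mm"),
    hdwi_levels = list(
      list(vpd = f(vpd_sfc, "vpd_sfc", "hPa"), wind_ms = f(wind_ms, "wind_sfc", "m/s")),
      list(vpd = f(vpd_up, "vpd_up", "hPa"), wind_ms = f(wind_up, "wind_up", "m/s"))
    )
  )
}

#' HDWI field from near-surface level stacks
#'
#' @param levels List of levels, each with `vpd` and `wind_ms`
#'   [grid_field()]s (as produced by [gen_surface()]).
#' @return A [grid_field()] of HDWI (hPa m/s).
#' @export
hdwi_field <- function(levels) {
  if (length(levels) == 0) stop("hdwi needs at least one level", call. = FALSE)
  vmax <- Reduce(pmax, lapply(levels, function(l) l$vpd$values))
  wmax <- Reduce(pmax, lapply(levels, function(l) l$wind_ms$values))
  ref <- levels[[1]]$vpd
  grid_field(vmax * wmax, ref$dates, ref$grid, variable = "hdwi",
             units = "hPa m/s")
}

#' Generate fire records with a known exposure odds ratio
#'
#' Exposure is the truth mask dilated by the configured lag; on exposed
#' cell-days the daily fire odds are the baseline odds times `or_true`,
#' otherwise the baseline `p0`. Burned areas are log-normal.
#'
#' @param truth A `synthetic_truth`.
#' @param config The same [synth_config()].
#' @param lag_days Exposure look-back, days (defaults to the config value).
#' @return Tibble `date`, `lat`, `lon`, `area_ha` (class keeps an
#'   `exposure` attribute: the lag-dilated truth exposure array).
#' @export
gen_fires <- function(truth, config, lag_days = config$fire_lag_days) {
  set.seed(config$seed + 2L)
  grid <- truth$grid
  dates <- truth$dates
  nt <- length(dates)
  n_cell <- grid$n_lat * grid$n_lon
  expo <- dilate_exposure(truth$mask, dates, lag_days)
  exf <- matrix(expo, nt, n_cell)
  odds0 <- config$p0 / (1 - config$p0)
  p1 <- (config$or_true * odds0) / (1 + config$or_true * odds0)
  if (p1 >= 1) stop("exposed fire probability reaches 1", call. = FALSE)
  p <- ifelse(exf, p1, config$p0)
  hit <- matrix(stats::runif(nt * n_cell), nt, n_cell) < p
  idx <- which(hit, arr.ind = TRUE)
  lat_cell <- rep(grid$lat, times = grid$n_lon)
  lon_cell <- rep(grid$lon, each = grid$n_lat)
  sizes <- stats::rlnorm(nrow(idx), log(config$fire_size_median_ha),
                         config$fire_size_sdlog)
  out <- tibble::tibble(
    date = dates[idx[, 1]],
    lat = lat_cell[idx[, 2]],
    lon = lon_cell[idx[, 2]],
    area_ha = sizes
  )
  out <- out[order(out$date, out$lat, out$lon), ]
  attr(out, "exposure") <- expo
  out
}

#' Simulate a full synthetic world
#'
#' Convenience wrapper: Z500 with injected events, coupled surface weather,
#' and fire records, all deterministically derived from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with `z500`, `truth`, `surface`, `fires`, `config`.
#' @export
simulate_world <- function(config = synth_config()) {
  z <- gen_z500(config)
  surface <- gen_surface(z$truth, config)
  fires <- gen_fires(z$truth, config)
  list(z500 = z$field, truth = z$truth, surface = surface, fires = fires,
       config = config)
}

#' Match detected events against the injected truth catalog
#'
#' For each injected event, finds the detected event sharing the most
#' cell-days with its core footprint (the half-prominence region where the
#' expected processed amplitude is at least midway between threshold and
#' peak; the skirt where the expected signal merely grazes the threshold is
#' flagged only about half the time by symmetric noise, so it measures
#' noise, not detector skill) and reports the coverage fraction and the
#' duration error. An injected event counts as recovered when at least half
#' its core cell-days are covered.
#'
#' @param events A `ppa_events` from [label_events()].
#' @param truth A `synthetic_truth` from [gen_z500()].
#' @return Tibble with one row per injected event: `event`, `coverage`,
#'   `recovered`, `duration_true`, `duration_detected`, `duration_error`.
#' @export
detection_recovery <- function(events, truth) {
  det <- attr(events, "detail")
  purrr::map_dfr(seq_along(truth$detail), function(i) {
    tr <- truth$detail[[i]]
    n_core <- sum(lengths(tr$core))
    best <- 0; best_dur <- NA_integer_
    for (d in det) {
      cov <- 0
      for (q in seq_along(tr$day_idx)) {
        pos <- match(tr$day_idx[q], d$day_idx)
        if (!is.na(pos)) {
          cov <- cov + length(intersect(tr$core[[q]], d$cells[[pos]]))
        }
      }
      if (cov > best) { best <- cov; best_dur <- length(d$day_idx) }
    }
    coverage <- if (n_core > 0) best / n_core else NA_real_
    tibble::tibble(
      event = i, coverage = coverage, recovered = !is.na(coverage) && coverage >= 0.5,
      duration_true = truth$catalog$duration_days[i],
      duration_detected = best_dur,
      duration_error = best_dur - truth$catalog$duration_days[i]
    )
  })
}
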