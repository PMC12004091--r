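#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis with its canonical default:
#' 5-day anomaly smoothing, 28-day threshold window, magnitude multiplier 1,
#' 5-day minimum duration, 40 000 km^2 minimum event area, 8-connectivity,
#' 7-day fire lag, +2 contingency correction, 95th FWIx percentile, 15-day
#' composite window, 45 degN reference latitude. A bare
#' `pipeline_config(sim = synth_config())` therefore runs the full analysis
#' under the default parameterization.
#'
#' @param sim Optional [synth_config()]: simulate the inputs.
#' @param z500,fires Optional input paths (long CSV / records CSV) used when
#'   `sim` is `NULL`.
#' @param regions A `ppa_regions` table, or `"quadrants"` for the built-in
#'   synthetic quadrant masks.
#' @param smoothing_window,threshold_window,multiplier,min_duration,min_event_area,connectivity,lag_days,correction,percentile,composite_window,ref_lat
#'   Algorithm parameters; see the linked stage functions.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, z500 = NULL, fires = NULL,
                            regions = "quadrants",
                            smoothing_window = 5, threshold_window = 28,
                            multiplier = 1, min_duration = 5,
                            min_event_area = 40000, connectivity = 8,
                            lag_days = 7, correction = 2, percentile = 0.95,
                            composite_window = 15, ref_lat = 45) {
  stopifnot(smoothing_window >= 1, smoothing_window %% 2 == 1,
            threshold_window >= 1, multiplier > 0, min_duration >= 1,
            min_event_area > 0, connectivity %in% c(4, 8), lag_days >= 0,
            correction >= 0, percentile > 0, percentile < 1,
            composite_window >= 1, ref_lat > 0, ref_lat <= 90)
  if (is.null(sim) && is.null(z500)) {
    stop("either a simulation config or a z500 input path is required",
         call. = FALSE)
  }
  structure(
    list(sim = sim, z500 = z500, fires = fires, regions = regions,
         smoothing_window = smoothing_window,
         threshold_window = threshold_window, multiplier = multiplier,
         min_duration = min_duration, min_event_area = min_event_area,
         connectivity = connectivity, lag_days = lag_days,
         correction = correction, percentile = percentile,
         composite_window = composite_window, ref_lat = ref_lat),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; an optional
#' `sim:` block holds [synth_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(synth_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full PPA--fire analysis pipeline
#'
#' Executes simulate/ingest, anomaly computation, event detection and
#' tracking, fire-weather indices, association statistics, and lead--lag
#' diagnostics in dependency order. When `out_dir` is given, every
#' figure-level quantity is written as delimited text together with a run
#' manifest (parameter values, package version, output digests) sufficient
#' to verify bit-reproducibility on fixed inputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress stage messages.
#' @return List of stage outputs: `z500`, `truth` (when simulated),
#'   `anomaly`, `threshold`, `events`, `exposure`, `pct_ppa_days`, `fwi`,
#'   `fwix`, `fires`, `or_fire`, `or_fwix`, `summary_fire`, `summary_fwix`,
#'   `attribution`, `composite`, `tstats`, `normality`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stopifnot(inherits(config, "pipeline_config"))

  ## inputs
  if (!is.null(config$sim)) {
    say("stage simulate: seed ", config$sim$seed)
    world <- simulate_world(config$sim)
    z500 <- world$z500
    surface <- world$surface
    fires <- world$fires
    truth <- world$truth
  } else {
    say("stage ingest: ", config$z500)
    z500 <- read_field_csv(config$z500, variable = "z500", units = "gpm")
    surface <- NULL
    truth <- NULL
    fires <- if (!is.null(config$fires)) {
      readr::read_csv(config$fires, show_col_types = FALSE)
    }
  }
  grid <- z500$grid
  regions <- if (identical(config$regions, "quadrants")) {
    region_quadrants(grid)
  } else config$regions

  ## anomalies and threshold: the magnitude threshold is the moving-window
  ## s.d. of the *unsmoothed* latitude-corrected anomaly; the smoothed
  ## series is what gets flagged against it
  say("stage anomalies")
  anom_raw <- compute_anomaly(z500, daily_climatology(z500))
  thr <- seasonal_threshold(latitude_correction(anom_raw, config$ref_lat),
                            config$threshold_window,
                            multiplier = config$multiplier)
  anom <- latitude_correction(
    smooth_time(anom_raw, config$smoothing_window), config$ref_lat)

  ## detection
  say("stage detect")
  flags <- flag_cells(anom, thr, config$min_duration)
  clusters <- cluster_daily(flags, config$connectivity)
  tracks <- track_clusters(clusters)
  events <- label_events(tracks, anom, config$min_event_area)
  say("  ", nrow(events), " event(s) labelled")
  expo <- ppa_day_mask(events, grid, z500$dates)

  ## fire weather
  fwi_out <- NULL; fwix <- NULL; surf_anom <- NULL
  if (!is.null(surface)) {
    say("stage fireweather")
    fwi_out <- cfwis_run(surface[c("temp", "rh", "wind", "prec")])
    fwi_out$hdwi <- hdwi_field(surface$hdwi_levels)
    fwix <- extreme_flags(fwi_out$fwi, q = config$percentile)
    surf_anom <- surface_anomalies(c(
      surface[c("temp", "prec", "wind")],
      fwi_out[c("vpd", "fwi", "ffmc", "dmc", "isi", "hdwi")]
    ))
  }

  ## association
  or_fire <- NULL; or_fwix <- NULL; summary_fire <- NULL; summary_fwix <- NULL
  attribution <- NULL; rast <- NULL
  if (!is.null(fires)) {
    say("stage associate")
    rast <- rasterize_fires(fires, grid, z500$dates)
    tab_fire <- classify_fire_days(expo$mask, rast$fire_day, config$lag_days)
    or_fire <- odds_ratio(tab_fire, config$correction)
    summary_fire <- regional_summary(or_fire, regions)
    attribution <- burned_area_attribution(rast$burned_area, expo$mask,
                                           config$lag_days, regions)
  }
  if (!is.null(fwix)) {
    tab_fwix <- classify_fwix_days(expo$mask, fwix$flags)
    or_fwix <- odds_ratio(tab_fwix, config$correction)
    summary_fwix <- regional_summary(or_fwix, regions)
  }

  ## diagnostics
  composite <- NULL; tstats <- NULL; normality <- NULL
  if (!is.null(surf_anom) && nrow(events) > 0) {
    say("stage diagnostics")
    composite <- leadlag_composite(events, surf_anom,
                                   burned_area = if (!is.null(rast)) rast$burned_area,
                                   window = config$composite_window)
    tstats <- dplyr::bind_rows(purrr::imap(
      surf_anom[c("temp", "vpd", "prec", "wind")],
      function(a, nm) ppa_effect_tstat(a, expo$mask, variable = nm)
    ))
    normality <- residual_normality_screen(surf_anom$temp, expo$mask)
    n_nonnorm <- sum(normality$p_value < 0.05, na.rm = TRUE)
    say("  normality screen: ", n_nonnorm, "/", nrow(normality),
        " sampled cell-months with Shapiro-Wilk p < 0.05")
  }

  out <- list(z500 = z500, truth = truth, anomaly = anom, threshold = thr,
              events = events, exposure = expo$mask,
              pct_ppa_days = expo$pct_ppa_days, fwi = fwi_out, fwix = fwix,
              fires = fires, or_fire = or_fire, or_fwix = or_fwix,
              summary_fire = summary_fire, summary_fwix = summary_fwix,
              attribution = attribution, composite = composite,
              tstats = tstats, normality = normality, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) {
      if (!is.null(x)) readr::write_csv(x, file.path(out_dir, nm))
    }
    wr(tibble::as_tibble(events), "events.csv")
    wr(out$pct_ppa_days, "pct_ppa_days.csv")
    wr(thr, "threshold.csv")
    wr(out$or_fire, "or_fire.csv")
    wr(out$or_fwix, "or_fwix.csv")
    if (!is.null(summary_fire)) wr(summary_fire$by_region, "summary_fire_region.csv")
    if (!is.null(summary_fwix)) wr(summary_fwix$by_region, "summary_fwix_region.csv")
    if (!is.null(attribution)) {
      wr(attribution$attribution, "attribution.csv")
      wr(attribution$lag_histogram, "burned_area_lag_histogram.csv")
    }
    wr(composite, "composite.csv")
    wr(tstats, "tstats.csv")
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest <- list(
      package = "ppafire",
      version = as.character(utils::packageVersion("ppafire")),
      parameters = config[setdiff(names(config), c("sim", "regions"))],
      sim = if (!is.null(config$sim)) unclass(config$sim),
      outputs = as.list(tools::md5sum(files))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  }
  invisible(out)
}
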