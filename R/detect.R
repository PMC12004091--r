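#' Flag persistent-anomaly cells
#'
#' A cell-day is flagged when it belongs to a run of at least `min_duration`
#' consecutive days on which the latitude-corrected anomaly meets or exceeds
#' `multiplier * threshold(calendar day)`. Runs never span a season (year
#' block) boundary. Missing anomalies break a run.
#'
#' @param anom A [grid_field()] at stage `"latitude_corrected"`.
#' @param thresholds A `ppa_threshold` from [seasonal_threshold()] (scalar
#'   per calendar day, or per-cell with `lat`/`lon` columns).
#' @param min_duration Minimum run length in days (default 5).
#' @return Logical array `[day, lat, lon]` with attributes `dates`, `grid`.
#' @export
flag_cells <- function(anom, thresholds, min_duration = 5) {
  if (min_duration < 1) stop("min_duration must be >= 1", call. = FALSE)
  if (!identical(anom$stage, "latitude_corrected")) {
    stop("flag_cells expects latitude-corrected anomalies", call. = FALSE)
  }
  mult <- attr(thresholds, "multiplier") %||% 1
  keys <- calday_key(anom$dates)
  mat <- flatten_field(anom$values)
  if ("lat" %in% names(thresholds)) {
    g <- anom$grid
    # per-cell thresholds: build [calday, cell] matrix aligned to the grid
    caldays <- sort(unique(thresholds$calday))
    thr_mat <- matrix(NA_real_, length(caldays), g$n_lat * g$n_lon)
    ii <- match(thresholds$lat, g$lat)
    jj <- match(thresholds$lon, g$lon)
    kk <- match(thresholds$calday, caldays)
    thr_mat[cbind(kk, (jj - 1L) * g$n_lat + ii)] <- thresholds$threshold
    thr_rows <- thr_mat[match(keys, caldays), , drop = FALSE]
    exceed <- !is.na(mat) & !is.na(thr_rows) & (mat >= mult * thr_rows)
  } else {
    thr <- thresholds$threshold[match(keys, thresholds$calday)]
    exceed <- !is.na(mat) & (mat >= mult * thr)
  }
  flags <- matrix(FALSE, nrow(mat), ncol(mat))
  for (block in split(seq_along(anom$dates), season_index(anom$dates))) {
    e <- exceed[block, , drop = FALSE]
    flags[block, ] <- apply(e, 2, function(x) {
      r <- rle(x)
      r$values <- r$values & r$lengths >= min_duration
      inverse.rle(r)
    })
  }
  out <- array(flags, c(nrow(mat), anom$grid$n_lat, anom$grid$n_lon))
  attr(out, "dates") <- anom$dates
  attr(out, "grid") <- anom$grid
  out
}

# connected-component labelling of one day's logical matrix.
# connectivity 4 (edges) or 8 (edges + corners). Iterative BFS; labels 1..k
# in order of first (column-major) appearance, 0 = background.
label_components <- function(mask, connectivity = 8) {
  n_lat <- nrow(mask); n_lon <- ncol(mask)
  lab <- matrix(0L, n_lat, n_lon)
  if (!any(mask)) return(lab)
  if (connectivity == 4) {
    di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  } else if (connectivity == 8) {
    di <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dj <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else stop("connectivity must be 4 or 8", call. = FALSE)
  nxt <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i0 <- ((cur - 1L) %% n_lat) + 1L
      j0 <- ((cur - 1L) %/% n_lat) + 1L
      ii <- i0 + di; jj <- j0 + dj
      ok <- ii >= 1L & ii <= n_lat & jj >= 1L & jj <= n_lon
      nb <- (jj[ok] - 1L) * n_lat + ii[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Label spatially contiguous flagged cells per day
#'
#' Connected-component labelling of the persistent-anomaly mask, one day at
#' a time. Diagonal contiguity (8-connectivity) is the default, as is
#' standard for synoptic-scale features.
#'
#' @param mask Output of [flag_cells()].
#' @param connectivity 4 (edge-sharing) or 8 (edge- or corner-sharing).
#' @return Integer array `[day, lat, lon]`; 0 = unflagged, labels count from
#'   1 within each day. Carries `dates`, `grid`, `connectivity` attributes.
#' @export
cluster_daily <- function(mask, connectivity = 8) {
  d <- dim(mask)
  out <- array(0L, d)
  for (t in seq_len(d[1])) {
    m <- matrix(mask[t, , ], d[2], d[3])
    if (any(m)) out[t, , ] <- label_components(m, connectivity)
  }
  attr(out, "dates") <- attr(mask, "dates")
  attr(out, "grid") <- attr(mask, "grid")
  attr(out, "connectivity") <- connectivity
  out
}

#' Track daily clusters through time
#'
#' Clusters on consecutive days are linked when they share at least one grid
#' cell. Each day-`t+1` cluster adopts as its main parent the overlapping
#' track with the largest previous-day area (ties broken by the older track
#' id); each track continues into its largest-area such child, other
#' children start new tracks carrying a parent link, and other parents
#' terminate with a child link (merge). A track interrupted for one or more
#' days ends; persistence is already enforced at the cell level.
#'
#' @param clusters Output of [cluster_daily()].
#' @return List of tracks (class `ppa_tracks`); each track is a list with
#'   `id`, `day_idx`, `dates`, `cells` (list of flat cell-index vectors),
#'   `area_km2`, `centroid_lat`, `centroid_lon`, `parent`, `merged_into`.
#' @export
track_clusters <- function(clusters) {
  dates <- attr(clusters, "dates")
  grid <- attr(clusters, "grid")
  areas <- cell_area_matrix(grid)
  lat_of <- rep(grid$lat, times = grid$n_lon)
  lon_of <- rep(grid$lon, each = grid$n_lat)
  nt <- dim(clusters)[1]
  seas <- season_index(dates)

  tracks <- list()
  n_tracks <- 0L
  # active: list of track ids alive at the previous day
  active <- integer(0)

  new_track <- function(day, cells, parent = NA_integer_) {
    n_tracks <<- n_tracks + 1L
    a <- sum(areas[cells])
    tracks[[n_tracks]] <<- list(
      id = n_tracks, day_idx = day, dates = dates[day], cells = list(cells),
      area_km2 = a,
      centroid_lat = sum(lat_of[cells] * areas[cells]) / a,
      centroid_lon = sum(lon_of[cells] * areas[cells]) / a,
      parent = parent, merged_into = NA_integer_
    )
    n_tracks
  }
  extend_track <- function(id, day, cells) {
    tr <- tracks[[id]]
    a <- sum(areas[cells])
    tr$day_idx <- c(tr$day_idx, day)
    tr$dates <- c(tr$dates, dates[day])
    tr$cells <- c(tr$cells, list(cells))
    tr$area_km2 <- c(tr$area_km2, a)
    tr$centroid_lat <- c(tr$centroid_lat, sum(lat_of[cells] * areas[cells]) / a)
    tr$centroid_lon <- c(tr$centroid_lon, sum(lon_of[cells] * areas[cells]) / a)
    tracks[[id]] <<- tr
  }

  for (t in seq_len(nt)) {
    labs <- matrix(clusters[t, , ], dim(clusters)[2], dim(clusters)[3])
    ids <- setdiff(sort(unique(as.integer(labs))), 0L)
    day_clusters <- lapply(ids, function(k) which(labs == k))
    # a season break severs all links
    if (t > 1 && seas[t] != seas[t - 1]) active <- integer(0)

    if (length(day_clusters) == 0) { active <- integer(0); next }
    if (length(active) == 0) {
      active <- vapply(day_clusters, function(cl) new_track(t, cl), 0L)
      next
    }
    prev_cells <- lapply(active, function(id) {
      tr <- tracks[[id]]
      tr$cells[[length(tr$cells)]]
    })
    prev_area <- vapply(active, function(id) {
      tr <- tracks[[id]]
      tr$area_km2[length(tr$area_km2)]
    }, 0)

    # main parent of each child cluster: overlapping track of largest area
    main_parent <- vapply(day_clusters, function(cl) {
      ov <- vapply(prev_cells, function(pc) length(intersect(pc, cl)) > 0, TRUE)
      if (!any(ov)) return(NA_integer_)
      cand <- which(ov)
      cand[order(-prev_area[cand], active[cand])][1]
    }, 0L)  # index into `active`, NA = orphan

    child_area <- vapply(day_clusters, function(cl) sum(areas[cl]), 0)
    next_active <- integer(0)
    for (p in seq_along(active)) {
      kids <- which(main_parent == p)
      if (length(kids) == 0) next  # track ends (no child or lost a merge)
      main_kid <- kids[order(-child_area[kids], kids)][1]
      extend_track(active[p], t, day_clusters[[main_kid]])
      next_active <- c(next_active, active[p])
      for (k in setdiff(kids, main_kid)) {
        next_active <- c(next_active,
                         new_track(t, day_clusters[[k]], parent = active[p]))
      }
    }
    # merged parents: overlapped some child but were not its main parent
    for (p in seq_along(active)) {
      if (active[p] %in% next_active) next
      ov_kid <- which(vapply(day_clusters, function(cl) {
        length(intersect(prev_cells[[p]], cl)) > 0
      }, TRUE))
      if (length(ov_kid) > 0) {
        winner <- main_parent[ov_kid[1]]
        tracks[[active[p]]]$merged_into <- active[winner]
      }
    }
    # orphan clusters start fresh tracks
    for (k in which(is.na(main_parent))) {
      next_active <- c(next_active, new_track(t, day_clusters[[k]]))
    }
    active <- next_active
  }
  structure(tracks, class = "ppa_tracks", grid = grid, dates = dates)
}

#' Label tracks as PPA events
#'
#' A track becomes an event when its daily area reaches `min_event_area` on
#' at least one day. Event duration is the full track lifespan (the size
#' criterion designates the tracked object, it does not truncate it; set
#' `duration_from_qualifying = TRUE` for the alternative). Daily strength is
#' the summed area-weighted anomaly magnitude over member cells
#' (gpm km^2), using the same latitude-corrected anomaly field that drove
#' detection.
#'
#' @param tracks A `ppa_tracks` from [track_clusters()].
#' @param anom The latitude-corrected anomaly [grid_field()].
#' @param min_event_area Minimum area, km^2 (default 40 000).
#' @param duration_from_qualifying If `TRUE`, clip the event to start at the
#'   first day the size criterion is met.
#' @return A `ppa_events` object: tibble with one row per event
#'   (`event_id`, `track_id`, `start`, `end`, `duration_days`,
#'   `max_area_km2`, `max_strength`, `max_strength_date`, `centroid_lat`,
#'   `centroid_lon`) plus per-day detail in `attr(, "detail")`. Events are
#'   ordered by start date, then west-to-east centroid.
#' @export
label_events <- function(tracks, anom, min_event_area = 40000,
                         duration_from_qualifying = FALSE) {
  grid <- attr(tracks, "grid")
  areas <- cell_area_matrix(grid)
  amat <- flatten_field(anom$values)
  detail <- list()
  rows <- list()
  for (tr in tracks) {
    qual <- tr$area_km2 >= min_event_area
    if (!any(qual)) next
    keep <- if (duration_from_qualifying) which(qual)[1]:length(tr$day_idx) else seq_along(tr$day_idx)
    day_idx <- tr$day_idx[keep]
    cells <- tr$cells[keep]
    strength <- vapply(seq_along(day_idx), function(i) {
      cl <- cells[[i]]
      sum(amat[day_idx[i], cl] * areas[cl])
    }, 0)
    imax <- which.max(strength)  # earliest tie wins (which.max semantics)
    detail[[length(detail) + 1L]] <- list(
      track_id = tr$id, day_idx = day_idx, dates = tr$dates[keep],
      cells = cells, area_km2 = tr$area_km2[keep], strength = strength,
      centroid_lat = tr$centroid_lat[keep], centroid_lon = tr$centroid_lon[keep]
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      track_id = tr$id,
      start = tr$dates[keep][1],
      end = tr$dates[keep][length(keep)],
      duration_days = length(keep),
      max_area_km2 = max(tr$area_km2[keep]),
      max_strength = strength[imax],
      max_strength_date = tr$dates[keep][imax],
      centroid_lat = tr$centroid_lat[keep][imax],
      centroid_lon = tr$centroid_lon[keep][imax]
    )
  }
  if (length(rows) == 0) {
    cat_tbl <- tibble::tibble(
      event_id = integer(), track_id = integer(),
      start = as.Date(character()), end = as.Date(character()),
      duration_days = integer(), max_area_km2 = numeric(),
      max_strength = numeric(), max_strength_date = as.Date(character()),
      centroid_lat = numeric(), centroid_lon = numeric()
    )
  } else {
    cat_tbl <- dplyr::bind_rows(rows)
    ord <- order(cat_tbl$start, cat_tbl$centroid_lon)
    cat_tbl <- cat_tbl[ord, ]
    detail <- detail[ord]
    cat_tbl <- dplyr::mutate(cat_tbl, event_id = dplyr::row_number(),
                             .before = 1)
  }
  structure(cat_tbl, detail = detail, grid = grid,
            dates = attr(tracks, "dates"),
            class = c("ppa_events", class(cat_tbl)))
}

#' Daily PPA exposure mask and percentage of PPA days
#'
#' A cell-day is exposed when the cell belongs to some labelled event's
#' cluster that day (membership in the labelled track counts even on days
#' the cluster is below the size threshold).
#'
#' @param events A `ppa_events` from [label_events()].
#' @param grid A [ppa_grid()] (defaults to the events' grid).
#' @param dates Analysis calendar (defaults to the events' calendar).
#' @return List with `mask` (logical `[day, lat, lon]`) and `pct_ppa_days`
#'   (tibble `lat`, `lon`, `month`, `pct`: average percentage of days in
#'   that calendar month, pooled across years, with a PPA overhead).
#' @export
ppa_day_mask <- function(events, grid = attr(events, "grid"),
                         dates = attr(events, "dates")) {
  nt <- length(dates)
  mask <- array(FALSE, c(nt, grid$n_lat, grid$n_lon))
  flat <- matrix(FALSE, nt, grid$n_lat * grid$n_lon)
  for (ev in attr(events, "detail")) {
    for (i in seq_along(ev$day_idx)) {
      flat[ev$day_idx[i], ev$cells[[i]]] <- TRUE
    }
  }
  mask <- array(flat, c(nt, grid$n_lat, grid$n_lon))
  mon <- month_of(dates)
  pct <- purrr::map_dfr(sort(unique(mon)), function(m) {
    rows <- which(mon == m)
    p <- 100 * colMeans(flat[rows, , drop = FALSE])
    tibble::tibble(
      lat = rep(grid$lat, times = grid$n_lon),
      lon = rep(grid$lon, each = grid$n_lat),
      month = m, pct = p
    )
  })
  attr(mask, "dates") <- dates
  attr(mask, "grid") <- grid
  list(mask = mask, pct_ppa_days = pct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
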