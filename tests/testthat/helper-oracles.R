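# Independent oracles used across the suite. These re-derive results through
# a different route than the package code: stack-based flood fill over
# explicit neighbour enumeration, a data-frame reimplementation of the
# documented overlap-chain tracking rule, and lm() for the t-statistic.

# flood fill with an explicit stack, one component at a time
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  neigh <- function(i, j) {
    if (connectivity == 4) {
      out <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    } else {
      out <- list()
      for (di in -1:1) for (dj in -1:1) {
        if (di != 0 || dj != 0) out[[length(out) + 1]] <- c(i + di, j + dj)
      }
    }
    out
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (q in neigh(p[1], p[2])) {
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# canonical relabelling so two labelings can be compared as partitions
normalize_labels <- function(lab) {
  ids <- unique(as.vector(lab))
  ids <- ids[ids != 0]
  out <- lab
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# independent tracking oracle: data-frame bookkeeping over the documented
# rule (link clusters sharing >= 1 cell on consecutive days; a child's main
# parent is the largest-area overlapping track, ties to the older track;
# a track continues into its largest-area main child; other main children
# start new tracks; season breaks sever links). Returns the partition of
# (day, label) cluster instances into tracks as a sorted list of key sets.
oracle_track_partition <- function(clusters) {
  dates <- attr(clusters, "dates")
  grid <- attr(clusters, "grid")
  areas <- matrix(ppafire::cell_area(grid$lat, grid$resolution),
                  grid$n_lat, grid$n_lon)
  seas <- as.integer(format(dates, "%Y"))
  nt <- dim(clusters)[1]
  inst <- list()   # per day: list of cell-index vectors by label
  for (t in seq_len(nt)) {
    labs <- matrix(clusters[t, , ], dim(clusters)[2], dim(clusters)[3])
    ids <- setdiff(sort(unique(as.integer(labs))), 0L)
    inst[[t]] <- lapply(ids, function(k) which(labs == k))
  }
  assign_df <- NULL   # day, cluster index, track id
  n_tracks <- 0L
  prev <- NULL        # data frame: track, area; plus list of cells
  prev_cells <- list()
  for (t in seq_len(nt)) {
    cl <- inst[[t]]
    if (t > 1 && seas[t] != seas[t - 1]) { prev <- NULL; prev_cells <- list() }
    if (length(cl) == 0) { prev <- NULL; prev_cells <- list(); next }
    main_parent <- rep(NA_integer_, length(cl))
    if (!is.null(prev)) {
      for (k in seq_along(cl)) {
        ov <- which(vapply(prev_cells, function(pc) any(pc %in% cl[[k]]), TRUE))
        if (length(ov)) {
          ord <- ov[order(-prev$area[ov], prev$track[ov])]
          main_parent[k] <- ord[1]
        }
      }
    }
    new_prev <- NULL; new_cells <- list()
    carea <- vapply(cl, function(x) sum(areas[x]), 0)
    if (!is.null(prev)) {
      for (p in seq_len(nrow(prev))) {
        kids <- which(main_parent == p)
        if (!length(kids)) next
        main_kid <- kids[order(-carea[kids], kids)][1]
        for (k in kids) {
          if (k == main_kid) {
            tid <- prev$track[p]
          } else {
            n_tracks <- n_tracks + 1L
            tid <- n_tracks
          }
          assign_df <- rbind(assign_df, data.frame(day = t, cluster = k, track = tid))
          new_prev <- rbind(new_prev, data.frame(track = tid, area = carea[k]))
          new_cells[[length(new_cells) + 1]] <- cl[[k]]
        }
      }
    }
    for (k in which(is.na(main_parent))) {
      n_tracks <- n_tracks + 1L
      assign_df <- rbind(assign_df, data.frame(day = t, cluster = k, track = n_tracks))
      new_prev <- rbind(new_prev, data.frame(track = n_tracks, area = carea[k]))
      new_cells[[length(new_cells) + 1]] <- cl[[k]]
    }
    prev <- new_prev; prev_cells <- new_cells
  }
  if (is.null(assign_df)) return(list())
  keys <- split(paste(assign_df$day, assign_df$cluster), assign_df$track)
  unname(keys[order(vapply(keys, function(x) x[1], ""))])
}

# partition of the package's tracks into the same (day, cluster) key space
package_track_partition <- function(tracks, clusters) {
  keys <- lapply(tracks, function(tr) {
    vapply(seq_along(tr$day_idx), function(i) {
      t <- tr$day_idx[i]
      labs <- matrix(clusters[t, , ], dim(clusters)[2], dim(clusters)[3])
      lab <- labs[tr$cells[[i]][1]]
      # cluster index within that day's sorted label list
      ids <- setdiff(sort(unique(as.integer(labs))), 0L)
      paste(t, match(lab, ids))
    }, "")
  })
  keys <- keys[vapply(keys, length, 0L) > 0]
  unname(keys[order(vapply(keys, function(x) x[1], ""))])
}

as_partition_set <- function(p) {
  sort(vapply(p, function(x) paste(sort(x), collapse = "|"), ""))
}

# season of daily dates for small fixtures
fixture_dates <- function(n, start = "2001-04-01") {
  seq(as.Date(start), by = "day", length.out = n)
}

# wrap a logical [day, lat, lon] array as a labelled-cluster input
make_clusters <- function(mask_arr, grid, dates, connectivity = 8) {
  attr(mask_arr, "dates") <- dates
  attr(mask_arr, "grid") <- grid
  cluster_daily(mask_arr, connectivity)
}

# standard detection chain used by several tests: anomalies, threshold from
# the unsmoothed latitude-corrected anomaly, flags on the smoothed series
detect_chain <- function(field, min_duration = 5, min_event_area = 40000,
                         connectivity = 8) {
  araw <- compute_anomaly(field, daily_climatology(field))
  thr <- seasonal_threshold(latitude_correction(araw), 28)
  anom <- latitude_correction(smooth_time(araw, 5))
  flags <- flag_cells(anom, thr, min_duration)
  clusters <- cluster_daily(flags, connectivity)
  tracks <- track_clusters(clusters)
  events <- label_events(tracks, anom, min_event_area)
  list(anom = anom, thr = thr, flags = flags, clusters = clusters,
       tracks = tracks, events = events)
}
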