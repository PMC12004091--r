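# build a latitude-corrected anomaly field and a flat unit threshold so that
# exceedance patterns can be scripted exactly
scripted_anom <- function(pattern, lat = 45, lon = 0, start = "2001-04-01") {
  # pattern: [day, cell] matrix of anomaly values
  g <- ppa_grid(lat, lon)
  dts <- fixture_dates(nrow(pattern), start)
  f <- grid_field(array(pattern, c(nrow(pattern), g$n_lat, g$n_lon)), dts, g,
                  stage = "latitude_corrected")
  thr <- tibble::tibble(calday = sort(unique(format(dts, "%m-%d"))),
                        threshold = 1)
  attr(thr, "multiplier") <- 1
  class(thr) <- c("ppa_threshold", class(thr))
  list(anom = f, thr = thr)
}

test_that("cells are flagged only inside runs of sufficient duration", {
  x <- rep(0, 12)
  x[3:8] <- 2                       # 6-day run
  s <- scripted_anom(matrix(x, ncol = 1))
  fl <- flag_cells(s$anom, s$thr, 5)
  expect_equal(which(fl[, 1, 1]), 3:8)

  x2 <- rep(0, 12); x2[3:6] <- 2    # 4-day run, below duration
  s2 <- scripted_anom(matrix(x2, ncol = 1))
  expect_false(any(flag_cells(s2$anom, s2$thr, 5)))

  # {5 days, gap, 5 days}: two flagged runs, gap day unflagged
  x3 <- c(rep(2, 5), 0, rep(2, 5))
  s3 <- scripted_anom(matrix(x3, ncol = 1))
  fl3 <- flag_cells(s3$anom, s3$thr, 5)
  expect_equal(which(fl3[, 1, 1]), c(1:5, 7:11))

  # brute-force run scan on random exceedance patterns
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(30, 0.8, 0.6)
    s <- scripted_anom(matrix(x, ncol = 1))
    fl <- flag_cells(s$anom, s$thr, 5)
    ex <- x >= 1
    brute <- logical(30)
    for (a in 1:26) {
      if (all(ex[a:(a + 4)])) {
        b <- a + 4
        while (b < 30 && ex[b + 1]) b <- b + 1
        brute[a:b] <- TRUE
      }
    }
    expect_identical(as.vector(fl[, 1, 1]), brute)
  }

  expect_error(flag_cells(s$anom, s$thr, 0), "min_duration")
})

test_that("runs never span a season boundary", {
  # 3 exceedance days ending season 1 + 3 starting season 2: no run of 5
  g <- ppa_grid(45, 0)
  dts <- c(fixture_dates(3, "2001-10-29"), fixture_dates(3, "2002-03-01"))
  f <- grid_field(array(2, c(6, 1, 1)), dts, g, stage = "latitude_corrected")
  thr <- tibble::tibble(calday = sort(unique(format(dts, "%m-%d"))), threshold = 1)
  attr(thr, "multiplier") <- 1
  class(thr) <- c("ppa_threshold", class(thr))
  expect_false(any(flag_cells(f, thr, 5)))
})

test_that("daily clustering honours 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[2, 3] <- TRUE  # edge-sharing
  expect_equal(max(label_components(m, 4)), 1)
  expect_equal(max(label_components(m, 8)), 1)

  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2] <- TRUE; m2[3, 3] <- TRUE  # corner-sharing
  expect_equal(max(label_components(m2, 8)), 1)
  expect_equal(max(label_components(m2, 4)), 2)
})

test_that("clustering equals a brute-force flood fill on random masks", {
  set.seed(31)
  for (i in 1:40) {
    m <- matrix(runif(15 * 15) < 0.3, 15, 15)
    for (conn in c(4, 8)) {
      expect_identical(normalize_labels(label_components(m, conn)),
                       normalize_labels(oracle_flood_fill(m, conn)))
    }
  }
})

test_that("tracking links overlapping clusters into coherent tracks", {
  g <- ppa_grid(lat = 40:49, lon = 0:9)
  dts <- fixture_dates(8)

  # stationary cluster for 6 days -> one track of duration 6
  arr <- array(FALSE, c(8, 10, 10))
  arr[1:6, 4:5, 4:5] <- TRUE
  cl <- make_clusters(arr, g, dts)
  tr <- track_clusters(cl)
  expect_length(tr, 1)
  expect_length(tr[[1]]$day_idx, 6)

  # cluster drifting one cell per day with overlap: one track, centroid
  # moves monotonically east
  arr2 <- array(FALSE, c(8, 10, 10))
  for (t in 1:6) arr2[t, 4:5, (2 + t):(3 + t)] <- TRUE
  tr2 <- track_clusters(make_clusters(arr2, g, dts))
  expect_length(tr2, 1)
  expect_true(all(diff(tr2[[1]]$centroid_lon) > 0))

  # two never-overlapping clusters -> two tracks
  arr3 <- array(FALSE, c(8, 10, 10))
  arr3[1:5, 2:3, 2:3] <- TRUE
  arr3[2:6, 8:9, 8:9] <- TRUE
  expect_length(track_clusters(make_clusters(arr3, g, dts)), 2)

  # a one-day interruption ends the track
  arr4 <- array(FALSE, c(8, 10, 10))
  arr4[c(1:3, 5:7), 4:5, 4:5] <- TRUE
  expect_length(track_clusters(make_clusters(arr4, g, dts)), 2)
})

test_that("tracking equals the independent overlap-chain oracle", {
  set.seed(32)
  g <- ppa_grid(lat = 40:49, lon = 0:9)
  for (i in 1:15) {
    dts <- fixture_dates(8)
    arr <- array(FALSE, c(8, 10, 10))
    # random drifting blobs plus sparse noise to provoke merges and splits
    n_blob <- sample(1:3, 1)
    for (b in seq_len(n_blob)) {
      ci <- runif(1, 3, 8); cj <- runif(1, 3, 8)
      di <- runif(1, -0.7, 0.7); dj <- runif(1, -0.7, 0.7)
      t0 <- sample(1:3, 1); t1 <- sample(5:8, 1)
      r <- runif(1, 1, 2.2)
      for (t in t0:t1) {
        ii <- matrix(rep(1:10, 10), 10)
        jj <- t(ii)
        arr[t, , ] <- arr[t, , ] |
          ((ii - (ci + di * t))^2 + (jj - (cj + dj * t))^2 <= r^2)
      }
    }
    arr <- arr | (array(runif(800), c(8, 10, 10)) < 0.02)
    cl <- make_clusters(arr, g, dts)
    tr <- track_clusters(cl)
    expect_identical(
      as_partition_set(package_track_partition(tr, cl)),
      as_partition_set(oracle_track_partition(cl))
    )
  }
})

test_that("events require the minimum size and report strength", {
  g <- ppa_grid(lat = 38:47, lon = 0:9)
  dts <- fixture_dates(10)
  # 5 cells at ~40N: area about 5 x 9470 = 47 350 km^2, above 40 000
  arr <- array(FALSE, c(10, 10, 10))
  arr[2:7, 3, 2:6] <- TRUE
  anom_vals <- array(0, c(10, 10, 10))
  anom_vals[2:7, 3, 2:6] <- 100
  anom <- grid_field(anom_vals, dts, g, stage = "latitude_corrected")
  tr <- track_clusters(make_clusters(arr, g, dts))
  ev <- label_events(tr, anom, 40000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_days, 6)
  area5 <- 5 * cell_area(40, 1)
  expect_equal(ev$max_area_km2, area5, tolerance = 1e-10)
  # uniform 100 gpm anomaly: strength = 100 x area
  expect_equal(ev$max_strength, 100 * area5, tolerance = 1e-10)

  # a track peaking below the size threshold is not an event
  ev2 <- label_events(tr, anom, 50000)
  expect_equal(nrow(ev2), 0)

  # duration_from_qualifying clips the pre-threshold days
  arr3 <- array(FALSE, c(10, 10, 10))
  arr3[2:3, 3, 2] <- TRUE               # small start
  arr3[4:7, 3, 2:6] <- TRUE             # grows to 5 cells
  tr3 <- track_clusters(make_clusters(arr3, g, dts))
  ev3a <- label_events(tr3, anom, 40000)
  ev3b <- label_events(tr3, anom, 40000, duration_from_qualifying = TRUE)
  expect_equal(ev3a$duration_days, 6)
  expect_equal(ev3b$duration_days, 4)
})

test_that("event counts fall as duration and size thresholds rise", {
  cfg <- synth_config(seed = 55, years = 2001:2002)
  z <- gen_z500(cfg)
  araw <- compute_anomaly(z$field, daily_climatology(z$field))
  thr <- seasonal_threshold(latitude_correction(araw), 28)
  anom <- latitude_correction(smooth_time(araw, 5))
  counts_dur <- vapply(c(3, 5, 8), function(d) {
    nrow(label_events(track_clusters(cluster_daily(flag_cells(anom, thr, d), 8)),
                      anom, 40000))
  }, 0L)
  expect_true(all(diff(counts_dur) <= 0))
  fl <- flag_cells(anom, thr, 5)
  trk <- track_clusters(cluster_daily(fl, 8))
  counts_area <- vapply(c(20000, 40000, 80000), function(a) {
    nrow(label_events(trk, anom, a))
  }, 0L)
  expect_true(all(diff(counts_area) <= 0))
})

test_that("exposure mask is the union of event footprints", {
  g <- ppa_grid(lat = 38:47, lon = 0:9)
  dts <- fixture_dates(30)  # April 2001: a 30-day month
  arr <- array(FALSE, c(30, 10, 10))
  arr[1:9, 3, 2:6] <- TRUE
  anom_vals <- array(0, c(30, 10, 10)); anom_vals[1:9, 3, 2:6] <- 100
  anom <- grid_field(anom_vals, dts, g, stage = "latitude_corrected")
  ev <- label_events(track_clusters(make_clusters(arr, g, dts)), anom, 40000)
  out <- ppa_day_mask(ev, g, dts)
  expect_identical(out$mask[, , ], arr[, , ])
  # covered 9 of 30 days in April -> 30%
  pct <- out$pct_ppa_days
  expect_equal(pct$pct[pct$lat == 40 & pct$lon == 2 & pct$month == 4], 30)
  expect_equal(sum(pct$pct > 0), 5)

  # no events -> all-false mask, 0% everywhere
  ev0 <- label_events(track_clusters(make_clusters(array(FALSE, c(30, 10, 10)),
                                                   g, dts)), anom, 40000)
  out0 <- ppa_day_mask(ev0, g, dts)
  expect_false(any(out0$mask))
  expect_true(all(out0$pct_ppa_days$pct == 0))
})
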