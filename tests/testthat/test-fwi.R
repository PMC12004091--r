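test_that("vapour pressure deficit follows the Magnus formula", {
  expect_equal(vpd(25, 100), 0)
  es25 <- 6.112 * exp(17.67 * 25 / (25 + 243.5))
  expect_equal(vpd(25, 0), es25)
  expect_equal(vpd(25, 40), es25 * 0.6)
  expect_error(vpd(25, 120), "\\[0, 100\\]")
  expect_error(vpd(25, -5), "\\[0, 100\\]")
  expect_true(all(vpd(seq(-10, 40, 5), 50) >= 0))
})

test_that("hot-dry-windy index multiplies level maxima", {
  expect_equal(hdwi(10, 5), 50)
  # maxima may come from different levels
  expect_equal(hdwi(c(10, 6), c(2, 8)), 80)
  expect_equal(hdwi(c(10, 6), c(0, 0)), 0)
  expect_error(hdwi(numeric(), numeric()), "at least one level")
  # homogeneous of degree 1 in wind
  v <- c(3, 7, 5); w <- c(2, 4, 1)
  expect_equal(hdwi(v, 2 * w), 2 * hdwi(v, w))
  # matrix form (levels x cells)
  vm <- rbind(c(10, 1), c(6, 2)); wm <- rbind(c(2, 3), c(8, 1))
  expect_equal(hdwi(vm, wm), c(80, 6))
})

test_that("one CFWIS step matches the independent oracle", {
  # canonical start-up day
  st <- fwi_init_state(1)
  out <- cfwis_step(st, temp = 20, rh = 40, wind = 15, prec = 0, month = 7)
  orc <- oracle_cfwis_step(85, 6, 15, 20, 40, 15, 0, 7)
  expect_equal(out$state$ffmc, orc$ffmc, tolerance = 0.1)
  expect_equal(out$state$dmc, orc$dmc, tolerance = 0.1)
  expect_equal(out$state$dc, orc$dc, tolerance = 0.1)
  expect_equal(out$isi, orc$isi, tolerance = 0.1)
  expect_equal(out$bui, orc$bui, tolerance = 0.1)
  expect_equal(out$fwi, orc$fwi, tolerance = 0.1)
})

test_that("CFWIS agrees with the oracle over a randomized weather grid", {
  set.seed(61)
  n <- 1000
  ffmc0 <- runif(n, 20, 99)
  dmc0 <- runif(n, 0, 120)
  dc0 <- runif(n, 0, 500)
  temp <- runif(n, -5, 38)
  rh <- runif(n, 5, 100)
  wind <- runif(n, 0, 60)
  prec <- ifelse(runif(n) < 0.4, rexp(n, 1 / 6), 0)
  month <- sample(3:10, n, replace = TRUE)
  worst <- 0
  for (i in seq_len(n)) {
    out <- cfwis_step(list(ffmc = ffmc0[i], dmc = dmc0[i], dc = dc0[i]),
                      temp[i], rh[i], wind[i], prec[i], month[i])
    orc <- oracle_cfwis_step(ffmc0[i], dmc0[i], dc0[i],
                             temp[i], rh[i], wind[i], prec[i], month[i])
    dev <- max(abs(c(out$state$ffmc - orc$ffmc, out$state$dmc - orc$dmc,
                     out$state$dc - orc$dc, out$isi - orc$isi,
                     out$bui - orc$bui, out$fwi - orc$fwi)))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 0.1)
})

test_that("rain wets all moisture codes relative to a dry counterfactual", {
  lattice <- expand.grid(ffmc = c(60, 85, 95), dmc = c(10, 60), dc = c(50, 300),
                         temp = c(10, 25), rh = c(30, 70))
  for (i in seq_len(nrow(lattice))) {
    p <- lattice[i, ]
    st <- list(ffmc = p$ffmc, dmc = p$dmc, dc = p$dc)
    wet <- cfwis_step(st, p$temp, p$rh, 10, 12, 7)
    dry <- cfwis_step(st, p$temp, p$rh, 10, 0, 7)
    expect_lt(wet$state$ffmc, dry$state$ffmc)
    expect_lt(wet$state$dmc, dry$state$dmc)
    expect_lt(wet$state$dc, dry$state$dc)
  }
})

test_that("spread index increases with dryness and wind", {
  st <- fwi_init_state(1)
  winds <- seq(0, 50, by = 5)
  isis <- vapply(winds, function(w) cfwis_step(st, 22, 35, w, 0, 7)$isi, 0)
  expect_true(all(diff(isis) > 0))
  # and in the previous day's FFMC (drier fine fuels spread faster)
  ffmcs <- seq(50, 99, by = 7)
  isis2 <- vapply(ffmcs, function(f) {
    cfwis_step(list(ffmc = f, dmc = 6, dc = 15), 22, 35, 10, 0, 7)$isi
  }, 0)
  expect_true(all(diff(isis2) > 0))
})

test_that("all components stay in their physical ranges", {
  set.seed(62)
  st <- fwi_init_state(200)
  for (d in 1:30) {
    out <- cfwis_step(st, runif(200, -5, 38), runif(200, 5, 100),
                      runif(200, 0, 60),
                      ifelse(runif(200) < 0.3, rexp(200, 0.2), 0),
                      sample(3:10, 1))
    st <- out$state
    expect_true(all(st$ffmc >= 0 & st$ffmc <= 101))
    expect_true(all(st$dmc >= 0))
    expect_true(all(st$dc >= 0))
    expect_true(all(out$isi >= 0 & out$bui >= 0 & out$fwi >= 0))
  }
})

test_that("the daily fold resets at season starts and matches the oracle", {
  set.seed(63)
  one_season <- function(start) {
    tibble::tibble(
      date = seq(as.Date(start), by = "day", length.out = 40),
      temp = runif(40, 8, 32), rh = runif(40, 15, 95),
      wind = runif(40, 0, 40),
      prec = ifelse(runif(40) < 0.3, rexp(40, 0.3), 0)
    )
  }
  wx1 <- one_season("2001-05-01")
  wx2 <- wx1; wx2$date <- wx1$date + 365
  out <- cfwis(rbind(wx1, wx2))
  # identical weather in two seasons gives identical indices (reset works)
  expect_equal(out$fwi[1:40], out$fwi[41:80], tolerance = 1e-12)
  expect_equal(out$dc[1:40], out$dc[41:80], tolerance = 1e-12)

  # fold equals a step-by-step oracle pass
  f <- 85; p <- 6; d <- 15
  for (t in 1:40) {
    orc <- oracle_cfwis_step(f, p, d, wx1$temp[t], wx1$rh[t], wx1$wind[t],
                             wx1$prec[t], as.integer(format(wx1$date[t], "%m")))
    f <- orc$ffmc; p <- orc$dmc; d <- orc$dc
    expect_equal(out$ffmc[t], f, tolerance = 1e-6)
    expect_equal(out$fwi[t], orc$fwi, tolerance = 1e-4)
  }

  # constant rain-free weather: DC never decreases within a season
  wx_dry <- tibble::tibble(date = seq(as.Date("2001-06-01"), by = "day",
                                      length.out = 30),
                           temp = 30, rh = 20, wind = 10, prec = 0)
  out_dry <- cfwis(wx_dry)
  expect_true(all(diff(out_dry$dc) >= 0))

  # a gap in the daily series errors
  wx_gap <- wx1[-5, ]
  expect_error(cfwis(wx_gap), "gap")
})

test_that("gridded CFWIS equals the per-cell tabular fold", {
  set.seed(64)
  g <- ppa_grid(lat = 44:45, lon = 0:1)
  dts <- fixture_dates(25, "2001-06-01")
  mk <- function(gen) grid_field(array(gen(25 * 4), c(25, 2, 2)), dts, g)
  weather <- list(
    temp = mk(function(n) runif(n, 10, 32)),
    rh = mk(function(n) runif(n, 20, 90)),
    wind = mk(function(n) runif(n, 0, 35)),
    prec = mk(function(n) ifelse(runif(n) < 0.25, rexp(n, 0.3), 0))
  )
  out <- cfwis_run(weather)
  cell_tab <- tibble::tibble(
    date = dts,
    temp = weather$temp$values[, 2, 1],
    rh = weather$rh$values[, 2, 1],
    wind = weather$wind$values[, 2, 1],
    prec = weather$prec$values[, 2, 1]
  )
  ref <- cfwis(cell_tab)
  expect_equal(out$fwi$values[, 2, 1], ref$fwi, tolerance = 1e-12)
  expect_equal(out$dc$values[, 2, 1], ref$dc, tolerance = 1e-12)
  expect_equal(out$vpd$values[, 2, 1], ref$vpd, tolerance = 1e-12)
})

test_that("extreme flags use the linear-interpolation 95th percentile", {
  g <- ppa_grid(45, 0)
  # 100 values in one calendar-month pool: 5 years of 20 May days
  dts <- do.call(c, lapply(2001:2005, function(y) {
    seq(as.Date(sprintf("%d-05-01", y)), by = "day", length.out = 20)
  }))
  f <- grid_field(array(1:100, c(100, 1, 1)), dts, g, variable = "fwi")
  out <- extreme_flags(f)
  expect_equal(out$thresholds$fwix_threshold, 95.05)
  expect_equal(sum(out$flags), 5)  # values 96..100 strictly exceed
  expect_equal(which(out$flags[, 1, 1]), 96:100)

  # constant pool: nothing strictly exceeds
  fc <- grid_field(array(7, c(100, 1, 1)), dts, g, variable = "fwi")
  expect_equal(sum(extreme_flags(fc)$flags), 0)

  # translation equivariance
  f2 <- grid_field(array(1:100 + 50, c(100, 1, 1)), dts, g, variable = "fwi")
  out2 <- extreme_flags(f2)
  expect_equal(out2$thresholds$fwix_threshold, 95.05 + 50)
  expect_identical(out2$flags[, 1, 1], out$flags[, 1, 1])

  # small pools warn
  dts_small <- seq(as.Date("2001-05-01"), by = "day", length.out = 10)
  fs <- grid_field(array(rnorm(10), c(10, 1, 1)), dts_small, g, variable = "fwi")
  expect_warning(extreme_flags(fs), "fewer than")
})

test_that("extreme flags mark about 5% of days in large pools", {
  set.seed(65)
  g <- ppa_grid(lat = 44:45, lon = 0:1)
  dts <- do.call(c, lapply(2001:2010, function(y) {
    seq(as.Date(sprintf("%d-06-01", y)), by = "day", length.out = 60)
  }))
  f <- grid_field(array(rgamma(length(dts) * 4, 2, 0.5), c(length(dts), 2, 2)),
                  dts, g, variable = "fwi")
  out <- extreme_flags(f)
  mon <- as.integer(format(dts, "%m"))
  for (m in unique(mon)) {
    frac <- colMeans(matrix(out$flags[mon == m, , ], sum(mon == m)))
    expect_true(all(frac > 0.04 & frac < 0.06))
  }
})
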