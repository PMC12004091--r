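# one-cell exposure/outcome fixture over April 2001 (a 30-day month)
april_masks <- function(ppa_days, fire_days) {
  g <- ppa_grid(45, 0)
  dts <- fixture_dates(30, "2001-04-01")
  ex <- array(FALSE, c(30, 1, 1)); ex[ppa_days, 1, 1] <- TRUE
  fo <- array(FALSE, c(30, 1, 1)); fo[fire_days, 1, 1] <- TRUE
  attr(ex, "dates") <- dts; attr(ex, "grid") <- g
  list(exposure = ex, outcome = fo, grid = g, dates = dts)
}

test_that("day-anchored classification reproduces the worked month", {
  # PPA days 1-10, fires on days 5 and 20, lag 7: exposed days are 1-17,
  # so a = 1 (day 5), b = 16, c = 1 (day 20), d = 12
  m <- april_masks(1:10, c(5, 20))
  tab <- classify_fire_days(m$exposure, m$outcome, lag_days = 7)
  expect_equal(tab$a, 1)
  expect_equal(tab$b, 16)
  expect_equal(tab$c, 1)
  expect_equal(tab$d, 12)
  expect_equal(tab$n, 30)

  # fire 2 days after the PPA ended is exposed (lag <= 7) ...
  m2 <- april_masks(2:8, 10)
  expect_equal(classify_fire_days(m2$exposure, m2$outcome, 7)$a, 1)
  # ... but a gap of 8 days is not
  m3 <- april_masks(2:8, 16)
  t3 <- classify_fire_days(m3$exposure, m3$outcome, 7)
  expect_equal(t3$a, 0)
  expect_equal(t3$c, 1)

  expect_error(classify_fire_days(m$exposure, m$outcome, -1), "non-negative")
})

test_that("classification partitions every analysed cell-day", {
  set.seed(71)
  g <- ppa_grid(lat = 40:44, lon = 0:4)
  dts <- do.call(c, lapply(2001:2002, function(y) {
    seq(as.Date(sprintf("%d-04-01", y)), by = "day", length.out = 75)
  }))
  nt <- length(dts)
  for (i in 1:5) {
    ex <- array(runif(nt * 25) < 0.2, c(nt, 5, 5))
    fo <- array(runif(nt * 25) < 0.05, c(nt, 5, 5))
    attr(ex, "dates") <- dts; attr(ex, "grid") <- g
    lag <- sample(0:7, 1)
    tab <- classify_days(ex, fo, lag)
    mon <- as.integer(format(dts, "%m"))
    for (m in unique(mon)) {
      expect_true(all(tab$n[tab$month == m] == sum(mon == m)))
    }
    # brute-force day enumeration on one random cell
    ci <- sample(5, 1); cj <- sample(5, 1)
    seas <- as.integer(format(dts, "%Y"))
    exposed <- logical(nt)
    for (t in seq_len(nt)) {
      back <- t - min(lag, t - 1)
      back <- max(back, min(which(seas == seas[t])))
      exposed[t] <- any(ex[back:t, ci, cj])
    }
    mm <- sample(unique(mon), 1)
    sel <- mon == mm
    row <- tab[tab$month == mm &
                 tab$lat == g$lat[ci] & tab$lon == g$lon[cj], ]
    expect_equal(row$a, sum(exposed[sel] & fo[sel, ci, cj]))
    expect_equal(row$c, sum(!exposed[sel] & fo[sel, ci, cj]))
  }
})

test_that("exposure grows weakly with the lag window", {
  set.seed(72)
  g <- ppa_grid(lat = 40:42, lon = 0:2)
  dts <- fixture_dates(60)
  ex <- array(runif(60 * 9) < 0.15, c(60, 3, 3))
  fo <- array(runif(60 * 9) < 0.05, c(60, 3, 3))
  attr(ex, "dates") <- dts; attr(ex, "grid") <- g
  exposed_count <- vapply(c(0, 3, 5, 7, 10), function(l) {
    tab <- classify_days(ex, fo, l)
    sum(tab$a + tab$b)
  }, 0)
  expect_true(all(diff(exposed_count) >= 0))
})

test_that("corrected odds ratios reproduce the worked tables", {
  tabs <- tibble::tibble(
    lat = 45, lon = 0, month = 4:6,
    a = c(10, 5, 4), b = c(90, 10, 6), c = c(10, 0, 3), d = c(90, 100, 7)
  )
  or <- odds_ratio(tabs, correction = 2)
  expect_equal(or$or, c(1, 29.75, 1.35))
  expect_false(any(or$insufficient_data))

  # no outcome days at all -> flagged, no OR
  or0 <- odds_ratio(tibble::tibble(lat = 45, lon = 0, month = 4,
                                   a = 0, b = 10, c = 0, d = 20), 2)
  expect_true(or0$insufficient_data)
  expect_true(is.na(or0$or))

  # correction -> 0 recovers the raw OR on tables with no zeros
  t1 <- tibble::tibble(lat = 45, lon = 0, month = 4, a = 8, b = 12, c = 5, d = 25)
  raw <- (8 * 25) / (12 * 5)
  ks <- c(2, 1, 0.5, 0.1, 0.01, 0)
  ors <- vapply(ks, function(k) odds_ratio(t1, k)$or, 0)
  expect_equal(ors[length(ks)], raw)
  expect_true(all(diff(abs(ors - raw)) <= 0))

  # inversion identity at k = 0: OR(a,b,c,d) = 1/OR(c,d,a,b)
  t2 <- tibble::tibble(lat = 45, lon = 0, month = 4, a = 5, b = 9, c = 3, d = 14)
  t2r <- tibble::tibble(lat = 45, lon = 0, month = 4, a = 3, b = 14, c = 5, d = 9)
  expect_equal(odds_ratio(t2, 0)$or, 1 / odds_ratio(t2r, 0)$or)
})

test_that("regional summaries aggregate cell-level odds ratios", {
  g <- ppa_grid(lat = 40:43, lon = 0:3)
  regions <- region_quadrants(g)
  # single cell with OR 3 in one region
  or1 <- odds_ratio(tibble::tibble(lat = 42, lon = 0, month = 6,
                                   a = 10, b = 10, c = 5, d = 22), 0)
  s1 <- regional_summary(or1, regions)
  expect_equal(s1$by_region$mean_or, 10 * 22 / (10 * 5))

  # cells {1, 3} average to 2
  or2 <- odds_ratio(tibble::tibble(lat = c(42, 42), lon = c(0, 1), month = 6,
                                   a = c(4, 6), b = c(4, 4), c = c(4, 2),
                                   d = c(4, 4)), 0)
  expect_equal(regional_summary(or2, regions)$by_region$mean_or, 2)

  # grouped means equal a brute-force group-by on a randomized fixture
  set.seed(73)
  cells <- expand.grid(lat = g$lat, lon = g$lon, month = 4:6)
  tabs <- tibble::as_tibble(cells)
  tabs$a <- rpois(nrow(tabs), 4) + 1
  tabs$b <- rpois(nrow(tabs), 20)
  tabs$c <- rpois(nrow(tabs), 3) + 1
  tabs$d <- rpois(nrow(tabs), 40)
  or3 <- odds_ratio(tabs, 2)
  s3 <- regional_summary(or3, regions)
  joined <- merge(as.data.frame(or3), as.data.frame(regions))
  brute <- tapply(joined$or, joined$region, mean)
  got <- setNames(s3$by_region$mean_or, s3$by_region$region)
  expect_equal(unname(got[names(brute)]), as.numeric(brute), tolerance = 1e-12)
  expect_equal(s3$overall, mean(brute), tolerance = 1e-12)
})

test_that("burned-area attribution splits exposed and unexposed hectares", {
  g <- ppa_grid(45, 0)
  dts <- fixture_dates(30, "2001-04-01")
  mk_ba <- function(days, ha) {
    v <- array(0, c(30, 1, 1)); v[days, 1, 1] <- ha
    grid_field(v, dts, g, variable = "burned_area", units = "ha")
  }
  ex <- array(FALSE, c(30, 1, 1)); ex[5:10, 1, 1] <- TRUE
  attr(ex, "dates") <- dts; attr(ex, "grid") <- g

  # all fires during PPA days -> 100%
  out <- burned_area_attribution(mk_ba(6:8, 50), ex, lag_days = 7)
  expect_equal(out$attribution$percent, 100)

  # no PPA -> 0%
  ex0 <- ex; ex0[] <- FALSE
  attr(ex0, "dates") <- dts; attr(ex0, "grid") <- g
  out0 <- burned_area_attribution(mk_ba(6:8, 50), ex0, lag_days = 7)
  expect_equal(out0$attribution$percent, 0)

  # mixed: fire on day 15 is within 5 days of the last PPA day (10), day 25 is not
  out_m <- burned_area_attribution(mk_ba(c(6, 15, 25), c(100, 50, 50)), ex, 7)
  expect_equal(out_m$attribution$ppa_burned_area_ha, 150)
  expect_equal(out_m$attribution$percent, 100 * 150 / 200)
  # lag histogram: day 6 during (lag 0), day 15 at lag 5, day 25 unexposed (NA)
  lh <- out_m$lag_histogram
  expect_equal(lh$burned_area_ha[match(0, lh$days_since_ppa)], 100)
  expect_equal(lh$burned_area_ha[match(5, lh$days_since_ppa)], 50)
  expect_equal(lh$burned_area_ha[is.na(lh$days_since_ppa)], 50)

  # zero burned area is flagged undefined
  out_z <- burned_area_attribution(mk_ba(integer(), numeric()), ex, 7)
  expect_true(is.na(out_z$attribution$percent))
})

test_that("glance on an OR table reports the pooled corrected estimate", {
  tabs <- tibble::tibble(lat = c(45, 45), lon = c(0, 1), month = 6,
                         a = c(10, 0), b = c(90, 5), c = c(10, 0), d = c(90, 55))
  or <- odds_ratio(tabs, 2)
  g <- glance(or)
  expect_equal(g$n_insufficient, 1)
  expect_equal(g$n_valid, 1)
  expect_equal(g$pooled_or, (10 + 2) * (145 + 2) / ((95 + 2) * (10 + 2)))
})
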