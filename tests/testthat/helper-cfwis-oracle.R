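# Scalar, step-by-step transliteration of the published fire-weather-index
# equations (Van Wagner's system definition), written in program-listing
# style as an independent cross-check of the vectorized package code.

oracle_ffmc <- function(ffmc_prev, temp, rh, wind, rain) {
  wmo <- 147.2 * (101 - ffmc_prev) / (59.5 + ffmc_prev)
  if (rain > 0.5) {
    ra <- rain - 0.5
    if (wmo > 150) {
      wmo <- wmo + 0.0015 * (wmo - 150)^2 * sqrt(ra) +
        42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    } else {
      wmo <- wmo + 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    }
    if (wmo > 250) wmo <- 250
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  if (wmo < ed && wmo < ew) {
    z <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
      0.0694 * sqrt(wind) * (1 - ((100 - rh) / 100)^8)
    x <- z * 0.581 * exp(0.0365 * temp)
    wm <- ew - (ew - wmo) / 10^x
  } else if (wmo > ed) {
    z <- 0.424 * (1 - (rh / 100)^1.7) +
      0.0694 * sqrt(wind) * (1 - (rh / 100)^8)
    x <- z * 0.581 * exp(0.0365 * temp)
    wm <- ed + (wmo - ed) / 10^x
  } else {
    wm <- wmo
  }
  ffmc <- 59.5 * (250 - wm) / (147.2 + wm)
  if (ffmc > 101) ffmc <- 101
  if (ffmc < 0) ffmc <- 0
  ffmc
}

oracle_dmc <- function(dmc_prev, temp, rh, rain, month) {
  el <- c(6.5, 7.5, 9, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8, 7, 6)
  t <- temp
  if (t < -1.1) t <- -1.1
  rk <- 1.894 * (t + 1.1) * (100 - rh) * el[month] * 1e-04
  pr <- dmc_prev
  if (rain > 1.5) {
    ra <- rain
    rw <- 0.92 * ra - 1.27
    wmi <- 20 + 280 / exp(0.023 * dmc_prev)
    if (dmc_prev <= 33) {
      b <- 100 / (0.5 + 0.3 * dmc_prev)
    } else if (dmc_prev <= 65) {
      b <- 14 - 1.3 * log(dmc_prev)
    } else {
      b <- 6.2 * log(dmc_prev) - 17.2
    }
    wmr <- wmi + 1000 * rw / (48.77 + b * rw)
    pr <- 43.43 * (5.6348 - log(wmr - 20))
    if (pr < 0) pr <- 0
  }
  pr + rk / 100 * 1e4 * 1e-02
}

oracle_dc <- function(dc_prev, temp, rain, month) {
  fl <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5, 2.4, 0.4, -1.6, -1.6)
  t <- temp
  if (t < -2.8) t <- -2.8
  pe <- (0.36 * (t + 2.8) + fl[month]) / 2
  if (pe < 0) pe <- 0
  dr <- dc_prev
  if (rain > 2.8) {
    ra <- rain
    rw <- 0.83 * ra - 1.27
    smi <- 800 * exp(-dc_prev / 400)
    dr <- dc_prev - 400 * log(1 + 3.937 * rw / smi)
    if (dr < 0) dr <- 0
  }
  dr + pe
}

oracle_isi <- function(ffmc, wind) {
  mo <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  ff <- 19.115 * exp(mo * -0.1386) * (1 + mo^5.31 / 4.93e07)
  ff * exp(0.05039 * wind)
}

oracle_bui <- function(dmc, dc) {
  if (dmc <= 0.4 * dc) {
    if (dmc + 0.4 * dc == 0) return(0)
    u <- 0.8 * dc * dmc / (dmc + 0.4 * dc)
  } else {
    u <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) *
      (0.92 + (0.0114 * dmc)^1.7)
  }
  max(u, 0)
}

oracle_fwi <- function(isi, bui) {
  if (bui > 80) {
    bb <- 0.1 * isi * (1000 / (25 + 108.64 / exp(0.023 * bui)))
  } else {
    bb <- 0.1 * isi * (0.626 * bui^0.809 + 2)
  }
  if (bb <= 1) bb else exp(2.72 * (0.434 * log(bb))^0.647)
}

oracle_cfwis_step <- function(ffmc0, dmc0, dc0, temp, rh, wind, rain, month) {
  f <- oracle_ffmc(ffmc0, temp, rh, wind, rain)
  p <- oracle_dmc(dmc0, temp, rh, rain, month)
  d <- oracle_dc(dc0, temp, rain, month)
  i <- oracle_isi(f, wind)
  b <- oracle_bui(p, d)
  list(ffmc = f, dmc = p, dc = d, isi = i, bui = b, fwi = oracle_fwi(i, b))
}
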