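# mean Earth radius, km; only relative areas matter for the size thresholds
EARTH_RADIUS_KM <- 6371.0

#' Spherical area of a grid cell
#'
#' Area of the latitude band slice `[lat - res/2, lat + res/2] x` one cell
#' width of longitude on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(lat + dphi/2) - sin(lat - dphi/2))`.
#'
#' @param lat_center Cell-centre latitude, degrees.
#' @param resolution Cell size, degrees.
#' @return Area in km^2; decreases with `|lat_center|`.
#' @examples
#' cell_area(0, 1)   # ~12364 km^2
#' cell_area(60, 1)  # ~ half of the equatorial value
#' @export
cell_area <- function(lat_center, resolution) {
  if (any(abs(lat_center) + resolution / 2 > 90 + 1e-12)) {
    stop("latitude band crosses a pole", call. = FALSE)
  }
  dlam <- resolution * pi / 180
  phi_hi <- (lat_center + resolution / 2) * pi / 180
  phi_lo <- (lat_center - resolution / 2) * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(phi_hi) - sin(phi_lo))
}

# per-cell area matrix [n_lat, n_lon] for a grid
cell_area_matrix <- function(grid) {
  matrix(cell_area(grid$lat, grid$resolution),
         nrow = grid$n_lat, ncol = grid$n_lon)
}

#' Conservative block-mean regridding
#'
#' Aggregates a fine field to a coarser resolution that is an integer
#' multiple of the source resolution. Each coarse value is the unweighted
#' mean of its constituent fine cells; missing fine cells are excluded, and
#' an all-missing block stays missing.
#'
#' @param field A [grid_field()].
#' @param target_resolution Coarse resolution, degrees.
#' @return A [grid_field()] on the coarse grid.
#' @export
regrid_mean <- function(field, target_resolution) {
  res <- field$grid$resolution
  fac <- target_resolution / res
  if (abs(fac - round(fac)) > 1e-8) {
    stop("target resolution must be an integer multiple of the source resolution",
         call. = FALSE)
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(field)
  g <- field$grid
  n_lat_c <- g$n_lat %/% fac
  n_lon_c <- g$n_lon %/% fac
  if (n_lat_c < 1 || n_lon_c < 1) stop("grid smaller than one coarse cell", call. = FALSE)
  # coarse centres are means of the member fine centres
  lat_c <- vapply(seq_len(n_lat_c), function(i) mean(g$lat[((i - 1) * fac + 1):(i * fac)]), 0)
  lon_c <- vapply(seq_len(n_lon_c), function(j) mean(g$lon[((j - 1) * fac + 1):(j * fac)]), 0)
  gc <- ppa_grid(lat_c, lon_c, resolution = target_resolution)
  nt <- length(field$dates)
  out <- array(NA_real_, c(nt, n_lat_c, n_lon_c))
  for (i in seq_len(n_lat_c)) {
    ri <- ((i - 1) * fac + 1):(i * fac)
    for (j in seq_len(n_lon_c)) {
      rj <- ((j - 1) * fac + 1):(j * fac)
      block <- field$values[, ri, rj, drop = FALSE]
      dim(block) <- c(nt, fac * fac)
      out[, i, j] <- rowMeans(block, na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  grid_field(out, field$dates, gc, variable = field$variable,
             units = field$units, stage = field$stage)
}

#' Rasterize point fire records onto the analysis grid
#'
#' Sums burned hectares per cell per day and derives the fire-day indicator.
#' Cell ownership is the half-open interval `[centre - res/2, centre + res/2)`
#' in both axes. Records outside the grid bounds or outside the field's
#' calendar are dropped and counted, not errored.
#'
#' @param records Data frame with columns `date`, `lat`, `lon`, `area_ha`
#'   (burned hectares, must be positive).
#' @param grid A [ppa_grid()].
#' @param dates `Date` vector defining the analysis calendar.
#' @return List with `burned_area` ([grid_field()], ha), `fire_day` (logical
#'   array `[day, lat, lon]`), and `n_dropped` (records outside grid/calendar).
#' @export
rasterize_fires <- function(records, grid, dates) {
  dates <- as.Date(dates)
  nt <- length(dates)
  ba <- array(0, c(nt, grid$n_lat, grid$n_lon))
  n_dropped <- 0L
  if (nrow(records) > 0) {
    if (any(records$area_ha <= 0)) {
      stop("burned_area must be positive for every record", call. = FALSE)
    }
    rdate <- as.Date(records$date)
    it <- match(rdate, dates)
    half <- grid$resolution / 2
    ii <- cell_bin(records$lat, grid$lat, half)
    jj <- cell_bin(records$lon, grid$lon, half)
    keep <- !is.na(it) & !is.na(ii) & !is.na(jj)
    n_dropped <- sum(!keep)
    if (any(keep)) {
      idx <- cbind(it[keep], ii[keep], jj[keep])
      sums <- tapply(records$area_ha[keep],
                     list(paste(idx[, 1], idx[, 2], idx[, 3])), sum)
      key <- do.call(rbind, lapply(strsplit(names(sums), " "), as.integer))
      ba[key] <- as.numeric(sums)
    }
  }
  if (n_dropped > 0) {
    message(n_dropped, " fire record(s) outside the grid/calendar dropped")
  }
  list(
    burned_area = grid_field(ba, dates, grid, variable = "burned_area", units = "ha"),
    fire_day = ba > 0,
    n_dropped = n_dropped
  )
}

# half-open bin assignment: index of the centre whose [c-half, c+half) box
# contains x, NA when outside the domain
cell_bin <- function(x, centers, half) {
  idx <- findInterval(x, centers - half, rightmost.closed = FALSE)
  idx[idx < 1L] <- NA_integer_
  idx[idx > length(centers)] <- NA_integer_
  # findInterval's upper edge is open except we must also reject beyond last bin
  out_hi <- !is.na(idx) & (x >= centers[pmin(idx, length(centers))] + half)
  idx[out_hi] <- NA_integer_
  idx
}

#' Region assignment for grid cells
#'
#' Builds a region map from a user-supplied table (`lat`, `lon`, `region`),
#' assigning every listed cell to at most one region; unlisted cells are
#' excluded from regional statistics.
#'
#' @param df Data frame with columns `lat`, `lon`, `region`.
#' @param grid A [ppa_grid()].
#' @return A tibble `lat`, `lon`, `region` restricted to grid cells, class
#'   `ppa_regions`.
#' @export
region_map <- function(df, grid) {
  out <- dplyr::distinct(tibble::as_tibble(df[c("lat", "lon", "region")]))
  if (anyDuplicated(out[c("lat", "lon")]) > 0) {
    stop("a cell is assigned to more than one region", call. = FALSE)
  }
  out <- dplyr::filter(out, .data$lat %in% grid$lat, .data$lon %in% grid$lon)
  class(out) <- c("ppa_regions", class(out))
  out
}

#' Quadrant region masks for a rectangular domain
#'
#' Synthetic stand-in for country-based regional masks: splits the domain at
#' its latitude/longitude midpoints into Northern, Southern, Eastern and
#' Western quadrants. Real analyses should supply their own region table via
#' [region_map()].
#'
#' @param grid A [ppa_grid()].
#' @return A `ppa_regions` tibble covering every cell.
#' @export
region_quadrants <- function(grid) {
  lat_mid <- mean(range(grid$lat))
  lon_mid <- mean(range(grid$lon))
  df <- expand.grid(lat = grid$lat, lon = grid$lon)
  df$region <- ifelse(df$lat >= lat_mid,
                      ifelse(df$lon < lon_mid, "Northern", "Eastern"),
                      ifelse(df$lon < lon_mid, "Western", "Southern"))
  region_map(df, grid)
}
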