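#' Regular latitude--longitude analysis grid
#'
#' Defines the cell-centre registered grid all gridded inputs live on.
#' Cell ownership is half-open: a point belongs to the cell whose interval
#' `[centre - res/2, centre + res/2)` contains it in both axes, so the grid
#' partitions the domain with no double counting.
#'
#' @param lat,lon Ascending, uniformly spaced cell-centre coordinates
#'   (degrees north / degrees east).
#' @param resolution Grid spacing in degrees. Defaults to the latitude step.
#' @return A `ppa_grid` object: list with `lat`, `lon`, `resolution`,
#'   `n_lat`, `n_lon`.
#' @examples
#' g <- ppa_grid(lat = 40:55, lon = 0:15)
#' g$n_lat
#' @export
ppa_grid <- function(lat, lon, resolution = NULL) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (length(lat) < 1 || length(lon) < 1) {
    stop("grid needs at least one latitude and one longitude", call. = FALSE)
  }
  if (is.null(resolution)) {
    resolution <- if (length(lat) > 1) diff(lat)[1] else if (length(lon) > 1) diff(lon)[1] else 1
  }
  check_uniform <- function(x, nm) {
    if (length(x) > 1) {
      d <- diff(x)
      if (any(d <= 0)) stop(nm, " must be strictly ascending", call. = FALSE)
      if (any(abs(d - resolution) > 1e-8)) {
        stop(nm, " spacing must equal the grid resolution", call. = FALSE)
      }
    }
  }
  check_uniform(lat, "lat")
  check_uniform(lon, "lon")
  if (any(abs(lat) + resolution / 2 > 90 + 1e-12)) {
    stop("latitude band crosses a pole", call. = FALSE)
  }
  structure(
    list(lat = lat, lon = lon, resolution = resolution,
         n_lat = length(lat), n_lon = length(lon)),
    class = "ppa_grid"
  )
}

#' @export
print.ppa_grid <- function(x, ...) {
  cat(sprintf("<ppa_grid> %d x %d cells at %g deg, lat %g..%g lon %g..%g\n",
              x$n_lat, x$n_lon, x$resolution,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Gridded day-by-cell field
#'
#' Container for one variable on a [ppa_grid()]: a numeric array indexed
#' `[day, lat, lon]` plus a calendar. Days must be contiguous within each
#' season (year block); seasons are delimited by the dates themselves.
#' Missing values are `NA`, never silent zeros.
#'
#' @param values Numeric array `[n_days, n_lat, n_lon]`.
#' @param dates `Date` vector, one per time slice.
#' @param grid A [ppa_grid()].
#' @param variable,units Labels carried through the pipeline.
#' @param stage Processing stage for anomaly fields: one of
#'   `"raw"`, `"smoothed"`, `"latitude_corrected"`, or `NA` for plain fields.
#' @return A `grid_field` object.
#' @export
grid_field <- function(values, dates, grid, variable = "value", units = "",
                       stage = NA_character_) {
  stopifnot(inherits(grid, "ppa_grid"))
  dates <- as.Date(dates)
  if (is.matrix(values)) values <- array(values, c(nrow(values), grid$n_lat, grid$n_lon))
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a [day, lat, lon] array", call. = FALSE)
  }
  d <- dim(values)
  if (d[1] != length(dates) || d[2] != grid$n_lat || d[3] != grid$n_lon) {
    stop("values dimensions do not match dates/grid", call. = FALSE)
  }
  if (!is.na(stage) &&
      !stage %in% c("raw", "smoothed", "latitude_corrected")) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  structure(
    list(values = values, dates = dates, grid = grid,
         variable = variable, units = units, stage = stage),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s] %d days x %d x %d cells%s\n",
              x$variable, x$units, length(x$dates), x$grid$n_lat, x$grid$n_lon,
              if (is.na(x$stage)) "" else paste0(", stage=", x$stage)))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

# season id: the calendar year of each date (seasons never span new year
# because the analysis window is March-October)
season_index <- function(dates) as.integer(format(dates, "%Y"))

# calendar-day key, leap-safe because the season excludes 29 Feb
calday_key <- function(dates) format(dates, "%m-%d")

month_of <- function(dates) as.integer(format(dates, "%m"))

# flatten helper: [day, lat, lon] -> [day, cell] (cell = column-major lat-fast)
flatten_field <- function(values) {
  d <- dim(values)
  dim(values) <- c(d[1], d[2] * d[3])
  values
}

unflatten_field <- function(mat, grid) {
  array(mat, c(nrow(mat), grid$n_lat, grid$n_lon))
}

#' Convert a gridded field to a long tibble
#'
#' @param x A [grid_field()].
#' @param ... Unused.
#' @return Tibble with columns `date`, `lat`, `lon`, `value`.
#' @export
as_tibble.grid_field <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    date = rep(x$dates, times = g$n_lat * g$n_lon),
    lat = rep(rep(g$lat, each = length(x$dates)), times = g$n_lon),
    lon = rep(g$lon, each = length(x$dates) * g$n_lat),
    value = as.vector(x$values)
  )
}

#' Build a gridded field from a long table
#'
#' Inverse of [as_tibble.grid_field()]: `df` must have one row per
#' (date, lat, lon) combination; absent combinations become `NA`.
#'
#' @param df Data frame with columns `date`, `lat`, `lon`, `value`.
#' @param grid Optional [ppa_grid()]; inferred from the coordinates if `NULL`.
#' @inheritParams grid_field
#' @return A [grid_field()].
#' @export
as_grid_field <- function(df, grid = NULL, variable = "value", units = "",
                          stage = NA_character_) {
  df$date <- as.Date(df$date)
  dates <- sort(unique(df$date))
  if (is.null(grid)) {
    grid <- ppa_grid(sort(unique(df$lat)), sort(unique(df$lon)))
  }
  vals <- array(NA_real_, c(length(dates), grid$n_lat, grid$n_lon))
  it <- match(df$date, dates)
  ii <- match(df$lat, grid$lat)
  jj <- match(df$lon, grid$lon)
  keep <- !is.na(it) & !is.na(ii) & !is.na(jj)
  vals[cbind(it[keep], ii[keep], jj[keep])] <- df$value[keep]
  grid_field(vals, dates, grid, variable = variable, units = units, stage = stage)
}

#' Read / write gridded fields as delimited text
#'
#' Long-format CSV with columns `date`, `lat`, `lon`, `value`; the
#' always-available plain-text interchange format for gridded data.
#'
#' @param x A [grid_field()].
#' @param path File path.
#' @return `write_field_csv()` returns `x` invisibly; `read_field_csv()`
#'   returns a [grid_field()].
#' @export
write_field_csv <- function(x, path) {
  readr::write_csv(as_tibble.grid_field(x), path)
  invisible(x)
}

#' @rdname write_field_csv
#' @inheritParams as_grid_field
#' @export
read_field_csv <- function(path, variable = "value", units = "",
                           stage = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_grid_field(df, variable = variable, units = units, stage = stage)
}

#' Read / write gridded fields as CF-style NetCDF
#'
#' Uses dimensions (time, latitude, longitude) with time as days since an
#' epoch. Requires the `ncdf4` package.
#'
#' @param x A [grid_field()].
#' @param path File path.
#' @param var_name Variable name inside the file (defaults to `x$variable`).
#' @return `write_field_nc()` returns `x` invisibly; `read_field_nc()` a
#'   [grid_field()].
#' @export
write_field_nc <- function(x, path, var_name = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("NetCDF I/O needs the 'ncdf4' package; use write_field_csv() otherwise",
         call. = FALSE)
  }
  if (is.null(var_name)) var_name <- x$variable
  g <- x$grid
  dim_lon <- ncdf4::ncdim_def("longitude", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("latitude", "degrees_north", g$lat)
  epoch <- as.Date("1970-01-01")
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(x$dates - epoch), unlim = TRUE)
  var <- ncdf4::ncvar_def(var_name, x$units, list(dim_lon, dim_lat, dim_time),
                          missval = 1e30)
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  # file layout is [lon, lat, time]
  ncdf4::ncvar_put(nc, var, aperm(x$values, c(3, 2, 1)))
  invisible(x)
}

#' @rdname write_field_nc
#' @inheritParams as_grid_field
#' @export
read_field_nc <- function(path, var_name = NULL, stage = NA_character_) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("NetCDF I/O needs the 'ncdf4' package; use read_field_csv() otherwise",
         call. = FALSE)
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(var_name)) var_name <- names(nc$var)[1]
  v <- nc$var[[var_name]]
  lon <- ncdf4::ncvar_get(nc, "longitude")
  lat <- ncdf4::ncvar_get(nc, "latitude")
  tvals <- as.numeric(ncdf4::ncvar_get(nc, "time"))
  dates <- as.Date("1970-01-01") + tvals
  arr <- ncdf4::ncvar_get(nc, var_name, collapse_degen = FALSE)
  vals <- aperm(arr, c(3, 2, 1))
  grid_field(vals, dates, ppa_grid(lat, lon), variable = var_name,
             units = v$units, stage = stage)
}
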