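#' Construct a rain grid object
#'
#' A \code{rain_grid} holds daily precipitation for a regular lon/lat grid:
#' cell-center coordinates, a gap-free sequence of calendar dates, and a
#' numeric matrix of rainfall depths (mm) with one row per day and one column
#' per cell. It is the synthetic stand-in for a blended satellite/station
#' precipitation product regridded to points.
#'
#' @param lon,lat numeric vectors of cell-center coordinates, one entry per
#'   cell (decimal degrees).
#' @param dates \code{Date} vector of consecutive calendar days.
#' @param values numeric matrix, \code{length(dates)} rows by
#'   \code{length(lon)} columns, non-negative rainfall in millimetres.
#' @return An object of class \code{rain_grid}.
#' @export
rain_grid <- function(lon, lat, dates, values) {
  values <- as.matrix(values)
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  if (nrow(values) != length(dates)) {
    stop("values must have one row per date")
  }
  if (ncol(values) != length(lon)) stop("values must have one column per cell")
  if (anyNA(values) || any(values < 0)) {
    stop("rainfall values must be non-negative and complete")
  }
  dd <- diff(as.integer(dates))
  if (length(dd) && any(dd != 1L)) stop("dates must be consecutive with no gaps")
  structure(
    list(
      cell_ids = seq_along(lon),
      lon = as.numeric(lon), lat = as.numeric(lat),
      dates = as.Date(dates), values = values
    ),
    class = "rain_grid"
  )
}

#' @export
print.rain_grid <- function(x, ...) {
  cat(sprintf(
    "rain_grid: %d cells, %d days (%s to %s)\n",
    length(x$cell_ids), length(x$dates),
    format(min(x$dates)), format(max(x$dates))
  ))
  cat(sprintf(
    "  lon [%.3f, %.3f], lat [%.3f, %.3f], mean daily %.2f mm\n",
    min(x$lon), max(x$lon), min(x$lat), max(x$lat), mean(x$values)
  ))
  invisible(x)
}

#' Simulate a daily precipitation grid with seasonal and interannual structure
#'
#' Generates a CHIRPS-like daily rainfall series on a regular lon/lat grid.
#' The generating model is multiplicative: a sinusoidal seasonal intensity
#' curve (the expected mm/day by day of year), scaled per cell and year by a
#' gamma-distributed anomaly with mean 1 and coefficient of variation
#' \code{interannual_cv} (so "drought years" are well-defined cell-years with
#' small multipliers), times optional day-level gamma noise with mean 1.
#' Expected annual total per cell is approximately \code{annual_mean_mm}.
#'
#' @param seed integer seed; the same seed and parameters reproduce the grid
#'   exactly.
#' @param n_years number of complete calendar years (must be at least 31 so a
#'   survey in the final year has a full 30-year lookback).
#' @param n_cells_x,n_cells_y grid dimensions.
#' @param seasonal_amplitude relative amplitude of the seasonal cycle in
#'   \code{[0, 1]}; 0 gives a flat climatology.
#' @param annual_mean_mm expected annual rainfall total per cell (mm).
#' @param interannual_cv coefficient of variation of the per-cell-per-year
#'   anomaly multiplier; 0 switches interannual variability off.
#' @param daily_cv coefficient of variation of day-level multiplicative noise;
#'   0 switches day noise off (days then follow the smooth seasonal curve).
#' @param start_year first calendar year of the series.
#' @param lon0,lat0,spacing grid origin and constant cell spacing in degrees.
#' @param peak_doy day of year at which the seasonal cycle peaks.
#' @return A \code{\link{rain_grid}}.
#' @examples
#' g <- simulate_rain_grid(1, n_years = 31, n_cells_x = 2, n_cells_y = 2)
#' g
#' @export
simulate_rain_grid <- function(seed, n_years = 40, n_cells_x = 10, n_cells_y = 10,
                               seasonal_amplitude = 0.8, annual_mean_mm = 900,
                               interannual_cv = 0.25, daily_cv = 1,
                               start_year = 1981, lon0 = 30, lat0 = -10,
                               spacing = 0.05, peak_doy = 32) {
  stop_if_not_scalar_number(seed, "seed")
  if (n_years < 31) stop("insufficient lookback: n_years must be >= 31")
  if (annual_mean_mm <= 0) stop("annual_mean_mm must be positive")
  if (interannual_cv < 0 || daily_cv < 0 || seasonal_amplitude < 0) {
    stop("seasonal_amplitude, interannual_cv and daily_cv must be non-negative")
  }
  if (seasonal_amplitude > 1) stop("seasonal_amplitude must be <= 1")

  n_cells <- n_cells_x * n_cells_y
  lon <- rep(lon0 + spacing * (seq_len(n_cells_x) - 1), times = n_cells_y)
  lat <- rep(lat0 + spacing * (seq_len(n_cells_y) - 1), each = n_cells_x)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)), by = "day")
  n_days <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1L
  year_idx <- as.POSIXlt(dates)$year + 1900L - start_year + 1L

  ## Seasonal expected intensity (mm/day); integrates to ~annual_mean_mm/year.
  base <- annual_mean_mm / 365
  seasonal <- base * (1 + seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365))

  with_seed(substream_seed(seed, "rain_grid"), {
    if (interannual_cv > 0) {
      shape_y <- 1 / interannual_cv^2
      anom <- matrix(stats::rgamma(n_years * n_cells, shape = shape_y,
                                   scale = 1 / shape_y),
                     nrow = n_years, ncol = n_cells)
    } else {
      anom <- matrix(1, nrow = n_years, ncol = n_cells)
    }
    values <- seasonal * anom[year_idx, , drop = FALSE]
    if (daily_cv > 0) {
      shape_d <- 1 / daily_cv^2
      noise <- matrix(stats::rgamma(n_days * n_cells, shape = shape_d,
                                    scale = 1 / shape_d),
                      nrow = n_days, ncol = n_cells)
      values <- values * noise
    }
    rain_grid(lon, lat, dates, values)
  })
}

#' Write / read a rain grid as long-format CSV
#'
#' Columns: \code{cell_id, lon, lat, date, mm} (ISO-8601 dates). This is the
#' plain-text interchange format for the gridded input; round-trips exactly to
#' the printed precision.
#'
#' @param grid a \code{\link{rain_grid}}.
#' @param path file path.
#' @return \code{read_rain_grid_csv} returns a \code{\link{rain_grid}}.
#' @export
write_rain_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "rain_grid"))
  df <- data.frame(
    cell_id = rep(grid$cell_ids, each = length(grid$dates)),
    lon = rep(grid$lon, each = length(grid$dates)),
    lat = rep(grid$lat, each = length(grid$dates)),
    date = rep(format(grid$dates), times = length(grid$cell_ids)),
    mm = as.vector(grid$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rain_grid_csv
#' @export
read_rain_grid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- sort(unique(df$cell_id))
  dates <- sort(unique(as.Date(df$date)))
  o <- order(df$cell_id, as.Date(df$date))
  df <- df[o, ]
  values <- matrix(df$mm, nrow = length(dates), ncol = length(cells))
  first <- !duplicated(df$cell_id)
  rain_grid(df$lon[first], df$lat[first], dates, values)
}
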