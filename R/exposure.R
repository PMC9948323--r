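#' Link a survey site to rainfall grid cells
#'
#' Maps a site's coordinates onto the grid either as the single nearest cell
#' (great-circle distance to cell centers; the default, appropriate when grid
#' cells are small relative to cluster-displacement error) or as a bilinear
#' weight set over the four surrounding cell centers (planar fractional
#' position, weights summing to 1).
#'
#' @param site one-row data frame (or list) with \code{lon} and \code{lat}.
#' @param grid a \code{\link{rain_grid}}.
#' @param method \code{"nearest"} or \code{"bilinear"}.
#' @return A list with \code{cells} (cell ids) and \code{weights}.
#' @export
link_site_to_cell <- function(site, grid, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "rain_grid"))
  slon <- site$lon[1]; slat <- site$lat[1]
  if (slon < min(grid$lon) || slon > max(grid$lon) ||
      slat < min(grid$lat) || slat > max(grid$lat)) {
    stop("site not covered by grid")
  }
  if (method == "nearest") {
    d <- haversine_m(slon, slat, grid$lon, grid$lat)
    i <- which.min(d)
    list(cells = grid$cell_ids[i], weights = 1)
  } else {
    lon_ax <- sort(unique(grid$lon)); lat_ax <- sort(unique(grid$lat))
    ix <- findInterval(slon, lon_ax, all.inside = TRUE)
    iy <- findInterval(slat, lat_ax, all.inside = TRUE)
    fx <- if (lon_ax[ix + 1] > lon_ax[ix]) {
      (slon - lon_ax[ix]) / (lon_ax[ix + 1] - lon_ax[ix])
    } else 0
    fy <- if (lat_ax[iy + 1] > lat_ax[iy]) {
      (slat - lat_ax[iy]) / (lat_ax[iy + 1] - lat_ax[iy])
    } else 0
    corners <- rbind(
      c(lon_ax[ix],     lat_ax[iy],     (1 - fx) * (1 - fy)),
      c(lon_ax[ix + 1], lat_ax[iy],     fx * (1 - fy)),
      c(lon_ax[ix],     lat_ax[iy + 1], (1 - fx) * fy),
      c(lon_ax[ix + 1], lat_ax[iy + 1], fx * fy)
    )
    cells <- vapply(seq_len(4), function(k) {
      which(grid$lon == corners[k, 1] & grid$lat == corners[k, 2])[1]
    }, integer(1))
    list(cells = grid$cell_ids[cells], weights = corners[, 3])
  }
}

## Great-circle (haversine) distance in metres; vectorized over points 2.
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Rainfall sum over the 12 months before a date
#'
#' Sums daily rainfall over the half-open window
#' \code{[end_date - n_days, end_date)}: the 365 days up to and including the
#' day before \code{end_date}; the anchor day itself is excluded. With a
#' bilinear linkage the per-day values are the weighted combination of the
#' linked cells.
#'
#' @param grid a \code{\link{rain_grid}}.
#' @param link a linkage from \code{\link{link_site_to_cell}} (or a bare cell
#'   id, taken with weight 1).
#' @param end_date anchor date (typically the interview date).
#' @param n_days window length in days (default 365).
#' @return The window rainfall total in millimetres.
#' @export
window_sum <- function(grid, link, end_date, n_days = 365) {
  if (!is.list(link)) link <- list(cells = link, weights = 1)
  end_date <- as.Date(end_date)
  i2 <- match(end_date - 1L, grid$dates)
  i1 <- match(end_date - n_days, grid$dates)
  if (is.na(i1) || is.na(i2)) stop("insufficient history for window ending ", format(end_date))
  cols <- match(link$cells, grid$cell_ids)
  sums <- colSums(grid$values[i1:i2, cols, drop = FALSE])
  sum(sums * link$weights)
}

#' Empirical percentile of the current annual rainfall against history
#'
#' Pools the current 12-month sum with the same window from the 29 previous
#' years and ranks all 30 values. Under the default \code{"pooled"}
#' convention the percentile is \code{(rank - 1) / 29} with ties taking the
#' mean of their tied ranks (midranks), so the driest year on record maps to
#' 0, the wettest to 1, and the pooled median to 0.5. Hazen
#' (\code{(rank - 0.5) / 30}) and Weibull (\code{rank / 31}) plotting
#' positions are available for sensitivity analyses.
#'
#' @param current current 12-month rainfall sum (mm).
#' @param historical numeric vector of exactly 29 historical sums (mm).
#' @param convention percentile convention.
#' @return A percentile in \code{[0, 1]}.
#' @examples
#' empirical_percentile(145, seq(10, 290, by = 10))
#' @export
empirical_percentile <- function(current, historical,
                                 convention = c("pooled", "hazen", "weibull")) {
  convention <- match.arg(convention)
  if (length(historical) != 29L) {
    stop("historical must contain exactly 29 values")
  }
  if (!is.finite(current) || !all(is.finite(historical))) {
    stop("rainfall sums must be finite")
  }
  pool <- c(current, historical)
  r <- rank(pool, ties.method = "average")[1]
  n <- length(pool)
  switch(convention,
    pooled = (r - 1) / (n - 1),
    hazen = (r - 0.5) / n,
    weibull = r / (n + 1)
  )
}

#' Build the exposure table for every unique site/interview-date pair
#'
#' For each unique (site, anchor date) combination among the respondents,
#' computes the 12-month pre-interview rainfall sum, the 29 historical sums
#' for the same 365-day window shifted back 1..29 whole calendar years
#' (preserving seasonal alignment; Feb-29 anchors clamp to Feb-28), and the
#' empirical percentile of the current sum within that 30-value pool.
#' Identical pairs are computed once and respondents join back by the
#' (site_id, anchor_date) key.
#'
#' @param grid a \code{\link{rain_grid}}.
#' @param sites site data frame with \code{site_id}, \code{lon}, \code{lat}.
#' @param respondents respondent data frame with \code{site_id} and
#'   \code{interview_date}.
#' @param method raster linkage method, see \code{\link{link_site_to_cell}}.
#' @param convention percentile convention, see
#'   \code{\link{empirical_percentile}}.
#' @return A data frame with one row per unique pair: \code{site_id},
#'   \code{anchor_date}, \code{annual_sum_mm}, \code{percentile}, and wide
#'   columns \code{hist_01}..\code{hist_29} (lag-year sums, most recent
#'   first).
#' @export
build_exposure_table <- function(grid, sites, respondents,
                                 method = c("nearest", "bilinear"),
                                 convention = c("pooled", "hazen", "weibull")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  stopifnot(inherits(grid, "rain_grid"))
  key <- unique(data.frame(site_id = respondents$site_id,
                           anchor_date = as.Date(respondents$interview_date),
                           stringsAsFactors = FALSE))
  key <- key[order(key$site_id, key$anchor_date), , drop = FALSE]
  rownames(key) <- NULL
  si <- match(key$site_id, sites$site_id)
  if (anyNA(si)) {
    stop("respondent site(s) missing from site table: ",
         paste(utils::head(unique(key$site_id[is.na(si)]), 5), collapse = ", "))
  }

  ## lookback check, reported for all offending pairs at once
  earliest_needed <- shift_years(key$anchor_date, -29L) - 365L
  bad <- earliest_needed < min(grid$dates) | key$anchor_date - 1L > max(grid$dates)
  if (any(bad)) {
    stop("insufficient 30-year lookback for pair(s): ",
         paste(sprintf("%s/%s", key$site_id[bad],
                       format(key$anchor_date[bad]))[seq_len(min(5, sum(bad)))],
               collapse = ", "))
  }

  ## one linkage per distinct site, cumulative sums per involved cell
  usites <- unique(key$site_id)
  links <- lapply(usites, function(s) {
    link_site_to_cell(sites[sites$site_id == s, ], grid, method)
  })
  names(links) <- usites
  cells_needed <- sort(unique(unlist(lapply(links, `[[`, "cells"))))
  csum <- apply(grid$values[, match(cells_needed, grid$cell_ids), drop = FALSE],
                2, cumsum)
  d0 <- as.integer(min(grid$dates)) - 1L
  wsum <- function(link, end_date) {
    ## half-open [end-365, end): cumulative difference per linked cell
    i2 <- as.integer(end_date) - 1L - d0
    i1 <- as.integer(end_date) - 365L - d0
    cols <- match(link$cells, cells_needed)
    hi <- csum[i2, cols]
    lo <- if (i1 >= 1L) csum[i1, cols] else 0
    sum((hi - lo) * link$weights)
  }

  n <- nrow(key)
  annual <- numeric(n)
  hist <- matrix(NA_real_, n, 29,
                 dimnames = list(NULL, sprintf("hist_%02d", 1:29)))
  for (i in seq_len(n)) {
    link <- links[[key$site_id[i]]]
    anchor <- key$anchor_date[i]
    annual[i] <- wsum(link, anchor)
    for (k in 1:29) hist[i, k] <- wsum(link, shift_years(anchor, -k))
  }
  perc <- vapply(seq_len(n), function(i) {
    empirical_percentile(annual[i], hist[i, ], convention)
  }, numeric(1))

  cbind(
    data.frame(site_id = key$site_id, anchor_date = key$anchor_date,
               annual_sum_mm = annual, percentile = perc,
               stringsAsFactors = FALSE),
    as.data.frame(hist)
  )
}

#' Join exposure percentiles back onto respondents
#'
#' @param respondents respondent data frame with \code{site_id} and
#'   \code{interview_date}.
#' @param exposure exposure table from \code{\link{build_exposure_table}}.
#' @return Respondents with \code{percentile} and \code{annual_sum_mm} added.
#' @export
attach_exposure <- function(respondents, exposure) {
  k1 <- paste(respondents$site_id, format(as.Date(respondents$interview_date)))
  k2 <- paste(exposure$site_id, format(exposure$anchor_date))
  m <- match(k1, k2)
  if (anyNA(m)) stop("respondents without an exposure record")
  respondents$percentile <- exposure$percentile[m]
  respondents$annual_sum_mm <- exposure$annual_sum_mm[m]
  respondents
}
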