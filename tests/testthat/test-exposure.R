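test_that("empirical percentile handles extremes, interior ranks and midranks", {
  hist <- seq(10, 290, by = 10)
  expect_equal(empirical_percentile(5, hist), 0)
  expect_equal(empirical_percentile(300, hist), 1)
  ## 145 slots between 140 and 150: rank 15 of 30
  expect_equal(empirical_percentile(145, hist), 14 / 29)
  ## exact tie with the value at sorted positions 15-16: midrank 15.5
  expect_equal(empirical_percentile(150, hist), 14.5 / 29)
  expect_error(empirical_percentile(100, hist[-1]), "exactly 29")
  expect_error(empirical_percentile(NaN, hist), "finite")
})

test_that("percentile matches the sort-and-midrank oracle on random draws", {
  set.seed(42)
  for (i in 1:200) {
    hist <- round(rgamma(29, 4, 1 / 200), 2)
    cur <- if (i %% 3 == 0) sample(hist, 1) else round(rgamma(1, 4, 1 / 200), 2)
    expect_identical(empirical_percentile(cur, hist),
                     oracle_percentile(cur, hist))
  }
})

test_that("percentile is invariant under strictly monotone transformations", {
  set.seed(1)
  hist <- rgamma(29, 3, 1 / 300)
  cur <- rgamma(1, 3, 1 / 300)
  p <- empirical_percentile(cur, hist)
  expect_equal(empirical_percentile(log(cur), log(hist)), p)
  expect_equal(empirical_percentile(3 * cur + 7, 3 * hist + 7), p)
})

test_that("alternative percentile conventions follow their plotting positions", {
  hist <- seq(10, 290, by = 10)
  expect_equal(empirical_percentile(145, hist, "hazen"), (15 - 0.5) / 30)
  expect_equal(empirical_percentile(145, hist, "weibull"), 15 / 31)
})

test_that("window sums match a naive day-loop on random windows", {
  g <- simulate_rain_grid(21, n_years = 31, n_cells_x = 3, n_cells_y = 3)
  expect_equal(window_sum(g, 1, g$dates[366] + 1),
               oracle_window_sum(g, 1, g$dates[366] + 1))
  set.seed(7)
  for (i in 1:20) {
    cell <- sample(g$cell_ids, 1)
    end <- sample(seq(g$dates[400], max(g$dates), by = "day"), 1)
    expect_equal(window_sum(g, cell, end), oracle_window_sum(g, cell, end),
                 tolerance = 1e-10)
  }
  ## all-zero rainfall
  z <- rain_grid(g$lon, g$lat, g$dates, matrix(0, length(g$dates), 9))
  expect_equal(window_sum(z, 1, g$dates[400]), 0)
  expect_error(window_sum(g, 1, g$dates[100]), "insufficient history")
})

test_that("nearest-cell linkage equals an exhaustive great-circle scan", {
  g <- simulate_rain_grid(22, n_years = 31, n_cells_x = 6, n_cells_y = 5)
  ## site exactly at a cell center resolves to that cell under both methods
  s0 <- list(lon = g$lon[8], lat = g$lat[8])
  expect_equal(link_site_to_cell(s0, g, "nearest")$cells, 8)
  bl <- link_site_to_cell(s0, g, "bilinear")
  expect_equal(sum(bl$weights), 1)
  expect_equal(bl$weights[bl$cells == 8], 1)
  set.seed(5)
  for (i in 1:100) {
    s <- list(lon = runif(1, min(g$lon), max(g$lon)),
              lat = runif(1, min(g$lat), max(g$lat)))
    expect_equal(link_site_to_cell(s, g, "nearest")$cells,
                 oracle_nearest_cell(s$lon, s$lat, g))
  }
  expect_error(link_site_to_cell(list(lon = 0, lat = 0), g), "not covered")
})

test_that("bilinear weights are symmetric at the cell-center midpoint", {
  g <- simulate_rain_grid(23, n_years = 31, n_cells_x = 2, n_cells_y = 2)
  s <- list(lon = mean(range(g$lon)), lat = mean(range(g$lat)))
  w <- link_site_to_cell(s, g, "bilinear")
  expect_equal(sort(w$cells), 1:4)
  expect_equal(unname(w$weights), rep(0.25, 4))
})

test_that("exposure table dedupes site/date pairs and ignores row order", {
  g <- simulate_rain_grid(24, n_years = 31, n_cells_x = 3, n_cells_y = 3)
  d <- dgp_spec(seed = 24, n_countries = 2, sites_per_country = 3,
                respondents_per_site = 10)
  sv <- simulate_survey(d, g)
  ## collapse to one interview date so 60 respondents yield 6 records
  sv$respondents$interview_date <- max(g$dates) - 10
  tab <- build_exposure_table(g, sv$sites, sv$respondents)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$percentile >= 0 & tab$percentile <= 1))
  expect_equal(ncol(tab), 4 + 29)

  shuffled <- sv$respondents[sample(nrow(sv$respondents)), ]
  expect_identical(build_exposure_table(g, sv$sites, shuffled), tab)

  joined <- attach_exposure(sv$respondents, tab)
  expect_false(anyNA(joined$percentile))
})

test_that("a driest-on-record final year maps to the bottom of the scale", {
  g <- simulate_rain_grid(25, n_years = 31, n_cells_x = 2, n_cells_y = 2,
                          interannual_cv = 0.2)
  ## force the last 365 days at cell 1 to (almost) no rainfall
  v <- g$values
  n <- nrow(v)
  v[(n - 364):n, 1] <- 0
  g2 <- rain_grid(g$lon, g$lat, g$dates, v)
  sites <- data.frame(site_id = "S1", lon = g$lon[1], lat = g$lat[1])
  resp <- data.frame(resp_id = "R1", site_id = "S1",
                     interview_date = max(g$dates) + 1)
  tab <- build_exposure_table(g2, sites, resp)
  expect_lte(tab$percentile, 1 / 29)
})

test_that("exposure table errors when the lookback is incomplete", {
  g <- simulate_rain_grid(26, n_years = 31, n_cells_x = 2, n_cells_y = 2)
  sites <- data.frame(site_id = "S1", lon = g$lon[1], lat = g$lat[1])
  resp <- data.frame(resp_id = "R1", site_id = "S1",
                     interview_date = min(g$dates) + 400)
  expect_error(build_exposure_table(g, sites, resp), "lookback.*S1")
})

test_that("percentiles from a stationary climate are near-uniform", {
  ## iid 30-value histories emulate many independent sites in a stationary
  ## climate; the pooled convention lives on the 30-point lattice
  ## 0, 1/29, ..., 1 and must hit all cells uniformly. A Kolmogorov-Smirnov
  ## comparison against continuous U(0,1) needs the randomized probability
  ## integral transform (uniform jitter within each lattice cell), which is
  ## exactly U(0,1) iff the ranks are uniform.
  set.seed(99)
  n <- 2000
  pooled <- numeric(n)
  for (i in seq_len(n)) {
    sums <- rgamma(30, 8, 1 / 100)
    pooled[i] <- empirical_percentile(sums[30], sums[1:29])
  }
  counts <- table(factor(round(pooled * 29), levels = 0:29))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  pit <- (round(pooled * 29) + runif(n)) / 30
  ks <- ks.test(pit, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pooled), 0.45)
  expect_lt(mean(pooled), 0.55)
})

test_that("grid-derived percentiles average near the median in-sample", {
  g <- simulate_rain_grid(27, n_years = 33, n_cells_x = 16, n_cells_y = 16,
                          interannual_cv = 0.25)
  d <- dgp_spec(seed = 27, n_countries = 6, sites_per_country = 100,
                respondents_per_site = 1)
  sv <- simulate_survey(d, g)
  tab <- build_exposure_table(g, sv$sites, sv$respondents)
  expect_gt(mean(tab$percentile), 0.45)
  expect_lt(mean(tab$percentile), 0.55)
})
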