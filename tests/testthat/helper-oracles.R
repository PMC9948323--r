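## Independent brute-force oracles used across tests. These deliberately
## re-derive each quantity from first principles, sharing no code with the
## package implementation.

## empirical percentile: explicit sort + midrank over the pooled 30 values
oracle_percentile <- function(current, historical) {
  pool <- sort(c(current, historical))
  pos <- which(abs(pool - current) < 1e-12)
  midrank <- mean(pos)
  (midrank - 1) / (length(pool) - 1)
}

## 365-day window sum: naive day-by-day accumulation
oracle_window_sum <- function(grid, cell, end_date, n_days = 365) {
  total <- 0
  for (k in seq_len(n_days)) {
    day <- as.Date(end_date) - k
    i <- which(grid$dates == day)
    total <- total + grid$values[i, cell]
  }
  total
}

## restricted cubic spline: direct truncated-power evaluation, one x at a time
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  cub <- function(u) if (u > 0) u^3 else 0
  out <- matrix(0, length(x), k - 1)
  for (r in seq_along(x)) {
    out[r, 1] <- x[r]
    for (j in 1:(k - 2)) {
      num <- cub(x[r] - knots[j]) -
        cub(x[r] - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
        cub(x[r] - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
      out[r, j + 1] <- num / (knots[k] - knots[1])^2
    }
  }
  out
}

## nearest grid cell by exhaustive great-circle scan (spherical law of cosines)
oracle_nearest_cell <- function(slon, slat, grid) {
  rad <- pi / 180
  d <- numeric(length(grid$lon))
  for (i in seq_along(grid$lon)) {
    cosang <- sin(slat * rad) * sin(grid$lat[i] * rad) +
      cos(slat * rad) * cos(grid$lat[i] * rad) * cos((slon - grid$lon[i]) * rad)
    d[i] <- acos(pmin(1, pmax(-1, cosang)))
  }
  grid$cell_ids[which.min(d)]
}

## marginal standardization: rebuild every counterfactual row explicitly via a
## fresh design at the forced percentile and average per-row predictions
oracle_marginal_prob <- function(fit, data, p) {
  data$percentile <- p
  des <- build_design(data, fit$design$knots,
                      include_interaction = length(fit$design$interaction_cols) > 0,
                      levels = fit$design$levels)
  probs <- numeric(nrow(des$X))
  for (i in seq_len(nrow(des$X))) {
    probs[i] <- 1 / (1 + exp(-sum(des$X[i, ] * fit$coef)))
  }
  mean(probs)
}

## small analysis-ready dataset shared by model-layer tests
make_small_study <- function(seed = 101, n_countries = 2, sites = 20,
                             per_site = 25, ...) {
  simulate_study(dgp_spec(seed = seed, n_countries = n_countries,
                          sites_per_country = sites,
                          respondents_per_site = per_site, ...))
}
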