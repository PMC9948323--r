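test_that("survey generation produces the requested nested structure", {
  d <- dgp_spec(seed = 2, n_countries = 2, sites_per_country = 3,
                respondents_per_site = 10)
  sv <- simulate_survey(d)
  expect_equal(nrow(sv$respondents), 60)
  expect_equal(nrow(sv$sites), 6)
  expect_true(all(sv$respondents$site_id %in% sv$sites$site_id))
  expect_true(all(table(sv$sites$country) >= 1))
  expect_false(anyNA(sv$respondents[c("age", "wealth_q", "hh_size_cat",
                                      "education", "literate", "married")]))
  expect_true(all(sv$respondents$age >= 15))
  expect_true(all(sv$respondents$wealth_q %in% 1:5))
  expect_true(all(sv$respondents$education %in%
                    c("none", "primary", "secondary", "higher")))
  expect_true(all(sv$respondents$hh_size_cat %in% c("1-2", "3-4", "5-7", "8+")))
})

test_that("interview dates leave a complete 30-year rainfall lookback", {
  g <- simulate_rain_grid(4, n_years = 31, n_cells_x = 3, n_cells_y = 3)
  d <- dgp_spec(seed = 4, n_countries = 2, sites_per_country = 10,
                respondents_per_site = 5)
  sv <- simulate_survey(d, g)
  anchors <- as.Date(sv$respondents$interview_date)
  earliest_needed <- rainmob:::shift_years(anchors, -29L) - 365L
  expect_true(all(earliest_needed >= min(g$dates)))
  expect_true(all(anchors > max(g$dates) - 366))
})

test_that("married share among women matches the calibrated 48.5%", {
  d <- dgp_spec(seed = 6, n_countries = 2, sites_per_country = 25,
                respondents_per_site = 1000, p_woman = 1)
  sv <- simulate_survey(d)
  n <- nrow(sv$respondents)
  expect_equal(n, 50000)
  se <- sqrt(0.485 * 0.515 / n)
  expect_lt(abs(mean(sv$respondents$married) - 0.485), 2 * se)
})

test_that("outcome prevalence calibrates to the baseline logit", {
  d <- dgp_spec(seed = 8, n_countries = 2, sites_per_country = 25,
                respondents_per_site = 1000, ushape_gamma = 0,
                covariate_betas = numeric(0), site_sd = 0,
                baseline_logit = qlogis(0.124))
  dat <- simulate_study(d)
  se <- sqrt(0.124 * 0.876 / nrow(dat))
  expect_lt(abs(mean(dat$mobile) - 0.124), 2 * se)
})

test_that("a U-shaped generating effect raises the rate in drought sites", {
  d <- dgp_spec(seed = 9, n_countries = 4, sites_per_country = 500,
                respondents_per_site = 50, ushape_gamma = 0.3,
                covariate_betas = numeric(0), site_sd = 0)
  dat <- simulate_study(d)
  expect_gte(nrow(dat), 100000)
  r_dry <- mean(dat$mobile[dat$percentile < 0.15])
  r_mid <- mean(dat$mobile[dat$percentile > 0.45 & dat$percentile < 0.55])
  expect_gt(r_dry, r_mid)
})

test_that("simulate_outcome validates percentiles and is seed-deterministic", {
  d <- dgp_spec(seed = 10, n_countries = 2, sites_per_country = 3,
                respondents_per_site = 5)
  sv <- simulate_survey(d)
  resp <- sv$respondents
  resp$urban <- sv$sites$urban[match(resp$site_id, sv$sites$site_id)]
  p_bad <- setNames(rep(1.2, 6), sv$sites$site_id)
  expect_error(simulate_outcome(d, resp, p_bad), "\\[0, 1\\]")
  p_ok <- setNames(runif(6), sv$sites$site_id)
  expect_identical(simulate_outcome(d, resp, p_ok)$mobile,
                   simulate_outcome(d, resp, p_ok)$mobile)
  expect_error(simulate_outcome(d, resp, p_ok[-1]), "no true percentile")
})

test_that("truth oracle: trivial identities and the closed-form limit", {
  d0 <- dgp_spec(seed = 11, ushape_gamma = 0, interaction_delta = 0)
  dat <- make_small_study(seed = 11)
  expect_equal(true_marginal_rr(d0, dat, 0.15, 0.5), 1.0)
  d1 <- dgp_spec(seed = 11, ushape_gamma = 0.4)
  expect_equal(true_marginal_rr(d1, dat, 0.3, 0.3), 1.0)

  ## no heterogeneity, no covariates: exact expit ratio
  d2 <- dgp_spec(seed = 11, ushape_gamma = 0.5, site_sd = 0,
                 covariate_betas = numeric(0), baseline_logit = qlogis(0.124))
  closed <- plogis(qlogis(0.124) + 0.5 * 4 * (0.15 - 0.5)^2) /
    plogis(qlogis(0.124) + 0.5 * 4 * (0.5 - 0.5)^2)
  expect_equal(true_marginal_rr(d2, dat, 0.15, 0.5), closed, tolerance = 1e-4)
  expect_error(true_marginal_rr(d2, dat, 0.15, 0.5, n_mc = 0), "n_mc")
})

test_that("whole-scenario generation is byte-identical under a fixed seed", {
  a <- make_small_study(seed = 12)
  b <- make_small_study(seed = 12)
  expect_identical(a, b)
})
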