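test_that("2x2 table recovers the closed-form logistic MLE", {
  ## counts: (x=1,y=1)=40, (x=1,y=0)=10, (x=0,y=1)=20, (x=0,y=0)=30
  x <- rep(c(1, 1, 0, 0), times = c(40, 10, 20, 30))
  y <- rep(c(1, 0, 1, 0), times = c(40, 10, 20, 30))
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_logistic(X, y, cluster = seq_along(y))
  expect_equal(unname(f$coef["x"]), log(6), tolerance = 1e-6)
  expect_equal(unname(f$coef["(Intercept)"]), log(20 / 30), tolerance = 1e-6)
})

test_that("IRLS agrees with glm and satisfies its convergence contract", {
  set.seed(14)
  n <- 800
  x <- rnorm(n); z <- rbinom(n, 1, 0.4)
  X <- cbind(`(Intercept)` = 1, x = x, z = z)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x - 0.5 * z))
  cl <- sample(sprintf("c%02d", 1:40), n, replace = TRUE)
  f <- fit_logistic(X, y, cl)
  g <- glm(y ~ x + z, family = binomial, control = list(epsilon = 1e-12))
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-8)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(f$aic, AIC(g), tolerance = 1e-8)
  expect_equal(f$aic, 2 * ncol(X) - 2 * f$loglik)
  expect_lt(f$gradient_norm, 1e-8)
  expect_true(all(diff(f$loglik_trace) >= -1e-10))
})

test_that("clustered sandwich matches the independent estimator", {
  skip_if_not_installed("sandwich")
  set.seed(15)
  n <- 600
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  cl <- sample(sprintf("c%02d", 1:30), n, replace = TRUE)
  u <- rnorm(30)[match(cl, sort(unique(cl)))]
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x + 0.7 * u))
  f <- fit_logistic(X, y, cl)
  g <- glm(y ~ x, family = binomial, control = list(epsilon = 1e-12))
  expect_equal(f$vcov_clustered,
               sandwich::vcovCL(g, cluster = cl, type = "HC0", cadjust = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
  ## CR0 drops the finite-cluster factor
  f0 <- fit_logistic(X, y, cl, cr = "CR0")
  expect_equal(f0$vcov_clustered * 30 / 29, f$vcov_clustered, tolerance = 1e-12)
})

test_that("singleton clusters reduce to HC0 times the finite-cluster factor", {
  set.seed(16)
  n <- 300
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- rbinom(n, 1, plogis(0.3 * x))
  f <- fit_logistic(X, y, cluster = seq_len(n))
  ## HC0 by hand: bread %*% (sum_i s_i s_i') %*% bread
  mu <- f$fitted
  bread <- f$vcov_naive
  S <- X * (y - mu)
  hc0 <- bread %*% crossprod(S) %*% bread
  expect_equal(f$vcov_clustered, hc0 * n / (n - 1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("degenerate and pathological inputs raise explicit errors", {
  X <- cbind(1, rnorm(50))
  expect_error(fit_logistic(X, rep(0, 50), 1:50), "one class")
  ## perfect separation
  x <- c(rep(-1, 25), rep(1, 25))
  y <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_logistic(cbind(1, x), y, 1:50), "separation")
  ## rank deficiency names the collinear column
  Xr <- cbind(`(Intercept)` = 1, a = x, b = 2 * x)
  expect_error(fit_logistic(Xr, rbinom(50, 1, 0.5), 1:50), "collinear.*b")
})

test_that("design matrix has the documented columns and codings", {
  dat <- make_small_study(seed = 31)
  ## force exactly 3 survey months
  dat$interview_date <- as.Date("2016-01-15") +
    sample(c(0, 31, 59), nrow(dat), replace = TRUE)
  des <- build_design(dat, knots = c(0.1, 0.5, 0.9))
  ## intercept + 2 spline + age + 4 wealth + 3 hh + 3 educ + literate +
  ## urban + married + 1 country + 2 month = 20
  expect_equal(ncol(des$X), 20)
  expect_equal(length(des$spline_cols), 2)
  des_i <- build_design(dat, knots = c(0.1, 0.5, 0.9), include_interaction = TRUE)
  expect_equal(ncol(des_i$X), 22)
  expect_equal(length(des_i$interaction_cols), 2)
  ## dummy coding partitions each categorical
  wcols <- grep("^wealth_q", colnames(des$X))
  expect_true(all(rowSums(des$X[, wcols]) %in% c(0, 1)))
  ecols <- grep("^educ_", colnames(des$X))
  expect_true(all(rowSums(des$X[, ecols]) %in% c(0, 1)))
  ## unseen level at prediction time errors
  dat2 <- dat[1:50, ]
  dat2$country <- "ZZ"
  expect_error(build_design(dat2, knots = c(0.1, 0.5, 0.9),
                            levels = des$levels), "unseen")
})

test_that("coefficients are consistent when the model is well specified", {
  ## generate the outcome from the fitted family itself (spline + covariates)
  ## and check per-coefficient bias against its Monte-Carlo standard error
  dat <- simulate_study(dgp_spec(seed = 33, n_countries = 4,
                                 sites_per_country = 100,
                                 respondents_per_site = 50, site_sd = 0))
  kn <- place_knots(dat$percentile, 3)
  des <- build_design(dat, kn)
  beta_true <- rep(0, ncol(des$X))
  names(beta_true) <- colnames(des$X)
  beta_true["(Intercept)"] <- qlogis(0.124)
  beta_true[des$spline_cols] <- c(0.5, -0.8)
  beta_true["age"] <- -0.01
  beta_true["married"] <- -0.25
  beta_true["urban"] <- 0.2
  eta <- drop(des$X %*% beta_true)
  R <- 25
  est <- matrix(NA_real_, R, length(beta_true))
  set.seed(34)
  for (r in seq_len(R)) {
    y <- rbinom(length(eta), 1, plogis(eta))
    est[r, ] <- fit_logistic(des$X, y, dat$site_id)$coef
  }
  bias <- colMeans(est) - beta_true
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_lt(max(abs(bias / mc_se)), 4)
})

test_that("AIC knot selection is parsimonious under linear truth", {
  picks <- sapply(1:20, function(r) {
    dat <- simulate_study(dgp_spec(seed = 600 + r, n_countries = 2,
                                   sites_per_country = 100,
                                   respondents_per_site = 50,
                                   ushape_gamma = 0, site_sd = 0))
    ## linear-in-percentile truth
    set.seed(700 + r)
    dat$mobile <- rbinom(nrow(dat), 1, plogis(qlogis(0.1) + 1.0 * dat$percentile))
    select_knots(dat, candidates = c(3, 4, 5))$k
  })
  expect_gt(mean(picks == 3), 0.5)
})

test_that("strong curvature produces a non-monotone fitted exposure curve", {
  dat <- simulate_study(dgp_spec(seed = 35, n_countries = 4,
                                 sites_per_country = 100,
                                 respondents_per_site = 50,
                                 ushape_gamma = 1.5, site_sd = 0))
  fit <- fit_mobility(dat, knots = "aic")
  cur <- marginal_curve(fit, seq(0.05, 0.95, by = 0.05))
  dirs <- sign(diff(cur$probability))
  expect_true(any(dirs < 0) && any(dirs > 0))
  i_min <- which.min(cur$probability)
  expect_gt(cur$p[i_min], 0.2)
  expect_lt(cur$p[i_min], 0.8)
})

test_that("fit_mobility validates inputs and reports its structure", {
  dat <- make_small_study(seed = 36)
  expect_error(fit_mobility(dat, gender = "other"), "woman")
  f <- fit_mobility(dat, knots = 3)
  expect_s3_class(f, "mobility_fit")
  expect_equal(f$n_clusters, length(unique(dat$site_id)))
  expect_equal(f$n_obs, nrow(dat))
  s <- summary(f)
  expect_true(all(c("Estimate", "Robust SE") %in% colnames(s$coefficients)))
  ## vcov accessor exposes both flavours
  expect_false(identical(vcov(f), vcov(f, type = "naive")))
  ## explicit knot vector is honoured
  f2 <- fit_mobility(dat, knots = c(0.2, 0.5, 0.8))
  expect_equal(f2$design$knots, c(0.2, 0.5, 0.8))
})
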