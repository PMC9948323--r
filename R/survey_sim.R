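#' Specify a synthetic data-generating process
#'
#' Bundles every parameter of the synthetic study: design sizes, the outcome
#' model on the logit scale, covariate effects, site-level heterogeneity, and
#' the master seed. The outcome model is
#' \deqn{logit P(mobile=1) = b_0 + \gamma\,4(p-0.5)^2 +
#'       \delta\,married\,4(p-0.5)^2 + x'\beta + u_{site},}
#' where \eqn{p} is the site's true rainfall percentile, \eqn{4(p-0.5)^2} is a
#' U-shaped exposure score equal to 0 at the median and 1 at either extreme,
#' and \eqn{u_{site} \sim N(0, site\_sd^2)} induces within-cluster correlation.
#' \code{ushape_gamma = 0} gives a null exposure effect; \code{interaction_delta}
#' adds effect modification by marital status on the quadratic term only.
#'
#' Covariate distributions are calibrated to the descriptive statistics of the
#' multi-country survey population the generator emulates: roughly 38% urban,
#' literacy 53% (women) / 67% (men), currently married 48.5% / 44.8%, wealth
#' quintiles near-uniform, and a right-skewed adult age distribution with mean
#' about 28.5 (women) / 30.7 (men) years.
#'
#' @param seed master integer seed; all stages derive sub-streams from it.
#' @param n_countries,sites_per_country,respondents_per_site design sizes.
#' @param baseline_logit intercept \eqn{b_0}; the default calibrates outcome
#'   prevalence to about 12.4% when exposure and covariate effects are off.
#' @param ushape_gamma coefficient \eqn{\gamma} on the U-shaped exposure score.
#'   The default 0.115 yields true drought and heavy-rain marginal risk ratios
#'   of about 1.05-1.06 against the median.
#' @param interaction_delta extra exposure coefficient \eqn{\delta} for married
#'   respondents (0 = no effect modification).
#' @param covariate_betas named numeric vector of covariate effects on the
#'   logit scale; recognised names: \code{age10} (per decade of age, centred
#'   at 30), \code{urban}, \code{married}, \code{literate},
#'   \code{educ_primary}, \code{educ_secondary}, \code{educ_higher},
#'   \code{wealth_q2}..\code{wealth_q5}, \code{hh_3_4}, \code{hh_5_7},
#'   \code{hh_8p}. Use \code{numeric(0)} for no covariate effects.
#' @param site_sd standard deviation of site-level random intercepts (logit
#'   scale); must be non-negative.
#' @param p_woman probability a respondent is a woman.
#' @return An object of class \code{dgp_spec}.
#' @export
dgp_spec <- function(seed = 1,
                     n_countries = 8,
                     sites_per_country = 50,
                     respondents_per_site = 100,
                     baseline_logit = stats::qlogis(0.124),
                     ushape_gamma = 0.115,
                     interaction_delta = 0,
                     covariate_betas = c(age10 = -0.15, urban = 0.15,
                                         married = -0.25, literate = 0.05),
                     site_sd = 0.3,
                     p_woman = 0.68) {
  stop_if_not_scalar_number(seed, "seed")
  if (site_sd < 0) stop("site_sd must be non-negative")
  if (n_countries < 1 || sites_per_country < 1 || respondents_per_site < 1) {
    stop("design counts must be >= 1")
  }
  if (length(covariate_betas) &&
      (is.null(names(covariate_betas)) || any(names(covariate_betas) == ""))) {
    stop("covariate_betas must be a named vector")
  }
  structure(
    list(
      seed = as.integer(seed), n_countries = as.integer(n_countries),
      sites_per_country = as.integer(sites_per_country),
      respondents_per_site = as.integer(respondents_per_site),
      baseline_logit = baseline_logit, ushape_gamma = ushape_gamma,
      interaction_delta = interaction_delta,
      covariate_betas = covariate_betas, site_sd = site_sd,
      p_woman = p_woman
    ),
    class = "dgp_spec"
  )
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat(sprintf(
    "dgp_spec: %d countries x %d sites x %d respondents (seed %d)\n",
    x$n_countries, x$sites_per_country, x$respondents_per_site, x$seed
  ))
  cat(sprintf(
    "  baseline_logit %.3f, ushape_gamma %.3f, interaction_delta %.3f, site_sd %.2f\n",
    x$baseline_logit, x$ushape_gamma, x$interaction_delta, x$site_sd
  ))
  invisible(x)
}

## Table-2-style covariate sampling parameters, by gender.
.covariate_calibration <- list(
  woman = list(
    married = 0.485, literate = 0.532,
    age_mean = 28.5, age_sd = 9.6,
    educ = c(none = 0.265, primary = 0.379, secondary = 0.316, higher = 0.040),
    hh = c(`1-2` = 0.070, `3-4` = 0.242, `5-7` = 0.401, `8+` = 0.287),
    wealth = c(0.190, 0.185, 0.190, 0.206, 0.229)
  ),
  man = list(
    married = 0.448, literate = 0.665,
    age_mean = 30.7, age_sd = 11.8,
    educ = c(none = 0.153, primary = 0.359, secondary = 0.415, higher = 0.073),
    hh = c(`1-2` = 0.132, `3-4` = 0.226, `5-7` = 0.373, `8+` = 0.269),
    wealth = c(0.183, 0.188, 0.195, 0.208, 0.227)
  ),
  urban = 0.38
)

## Draw ages as 15 + gamma, matching a target mean/sd for the adult range.
.draw_age <- function(n, mean, sd) {
  m <- mean - 15
  shape <- (m / sd)^2
  15 + stats::rgamma(n, shape = shape, scale = sd^2 / m)
}

#' Generate sites and respondents (covariates only, no outcome)
#'
#' Places survey clusters (sites) uniformly over the interior of the rainfall
#' grid, assigns them to countries in contiguous blocks, draws one interview
#' date per site within the final 12 months of the grid span (always leaving a
#' complete 30-year rainfall lookback), and samples respondent covariates from
#' gender-specific calibrated distributions.
#'
#' When \code{grid} is \code{NULL} the geographic stage is skipped: sites get
#' unit-square placeholder coordinates and interview dates spread over a
#' nominal survey year. This is the fast path for simulation studies that
#' supply true exposure percentiles directly.
#'
#' @param dgp a \code{\link{dgp_spec}}.
#' @param grid optional \code{\link{rain_grid}} spanning at least 31 years.
#' @return A list with data frames \code{sites} (site_id, lon, lat, country,
#'   urban, interview_date) and \code{respondents} (resp_id, site_id, gender,
#'   interview_date, age, wealth_q, hh_size_cat, education, literate, married).
#' @export
simulate_survey <- function(dgp, grid = NULL) {
  stopifnot(inherits(dgp, "dgp_spec"))
  n_sites <- dgp$n_countries * dgp$sites_per_country
  n_resp <- n_sites * dgp$respondents_per_site

  if (!is.null(grid)) {
    stopifnot(inherits(grid, "rain_grid"))
    if (length(grid$cell_ids) == 0L) stop("empty grid")
    span_years <- as.numeric(max(grid$dates) - min(grid$dates)) / 365.25
    if (span_years < 30.9) stop("grid must span at least 31 years")
  }

  with_seed(substream_seed(dgp$seed, "survey"), {
    if (!is.null(grid)) {
      ## keep sites off the outermost ring of cells so bilinear linkage works
      lon_r <- range(grid$lon); lat_r <- range(grid$lat)
      mlon <- if (diff(lon_r) > 0) 0.05 * diff(lon_r) else 0
      mlat <- if (diff(lat_r) > 0) 0.05 * diff(lat_r) else 0
      s_lon <- stats::runif(n_sites, lon_r[1] + mlon, lon_r[2] - mlon)
      s_lat <- stats::runif(n_sites, lat_r[1] + mlat, lat_r[2] - mlat)
      ## interview in the final 12 months, with a full 30-year lookback:
      ## window sums need [anchor - 29y - 365d, anchor)
      last <- max(grid$dates)
      earliest_ok <- max(last - 364L,
                         shift_years(min(grid$dates), 29L) + 365L)
      if (earliest_ok > last) stop("grid too short for a 30-year lookback")
      date_pool <- seq(earliest_ok, last, by = "day")
    } else {
      s_lon <- stats::runif(n_sites)
      s_lat <- stats::runif(n_sites)
      date_pool <- seq(as.Date("2016-01-01"), as.Date("2016-12-31"), by = "day")
    }
    sites <- data.frame(
      site_id = sprintf("S%05d", seq_len(n_sites)),
      lon = s_lon, lat = s_lat,
      country = sprintf("C%02d", rep(seq_len(dgp$n_countries),
                                     each = dgp$sites_per_country)),
      urban = stats::rbinom(n_sites, 1, .covariate_calibration$urban),
      interview_date = sample(date_pool, n_sites, replace = TRUE),
      stringsAsFactors = FALSE
    )

    gender <- ifelse(stats::rbinom(n_resp, 1, dgp$p_woman) == 1, "woman", "man")
    resp <- data.frame(
      resp_id = sprintf("R%07d", seq_len(n_resp)),
      site_id = rep(sites$site_id, each = dgp$respondents_per_site),
      gender = gender,
      interview_date = rep(sites$interview_date, each = dgp$respondents_per_site),
      age = NA_real_, wealth_q = NA_integer_, hh_size_cat = NA_character_,
      education = NA_character_, literate = NA_integer_, married = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (g in c("woman", "man")) {
      cal <- .covariate_calibration[[g]]
      idx <- which(gender == g)
      n_g <- length(idx)
      if (!n_g) next
      resp$age[idx] <- .draw_age(n_g, cal$age_mean, cal$age_sd)
      resp$wealth_q[idx] <- sample.int(5L, n_g, replace = TRUE, prob = cal$wealth)
      resp$hh_size_cat[idx] <- sample(names(cal$hh), n_g, replace = TRUE,
                                      prob = cal$hh)
      resp$education[idx] <- sample(names(cal$educ), n_g, replace = TRUE,
                                    prob = cal$educ)
      resp$literate[idx] <- stats::rbinom(n_g, 1, cal$literate)
      resp$married[idx] <- stats::rbinom(n_g, 1, cal$married)
    }
    list(sites = sites, respondents = resp)
  })
}

## U-shaped exposure score: 0 at the median percentile, 1 at either extreme.
ushape_score <- function(p) 4 * (p - 0.5)^2

## Covariate contribution to the outcome logit, from a named beta vector.
dgp_covariate_linpred <- function(dgp, respondents) {
  betas <- dgp$covariate_betas
  if (!length(betas)) return(numeric(nrow(respondents)))
  cols <- list(
    age10 = function(d) (d$age - 30) / 10,
    urban = function(d) d$urban,
    married = function(d) d$married,
    literate = function(d) d$literate,
    educ_primary = function(d) as.numeric(d$education == "primary"),
    educ_secondary = function(d) as.numeric(d$education == "secondary"),
    educ_higher = function(d) as.numeric(d$education == "higher"),
    wealth_q2 = function(d) as.numeric(d$wealth_q == 2L),
    wealth_q3 = function(d) as.numeric(d$wealth_q == 3L),
    wealth_q4 = function(d) as.numeric(d$wealth_q == 4L),
    wealth_q5 = function(d) as.numeric(d$wealth_q == 5L),
    hh_3_4 = function(d) as.numeric(d$hh_size_cat == "3-4"),
    hh_5_7 = function(d) as.numeric(d$hh_size_cat == "5-7"),
    hh_8p = function(d) as.numeric(d$hh_size_cat == "8+")
  )
  unknown <- setdiff(names(betas), names(cols))
  if (length(unknown)) {
    stop("unknown covariate_betas names: ", paste(unknown, collapse = ", "))
  }
  ## respondents whose site covariate carries urban: merge expected upstream
  lp <- numeric(nrow(respondents))
  for (nm in names(betas)) lp <- lp + betas[[nm]] * cols[[nm]](respondents)
  lp
}

#' Draw the binary mobility outcome from the generating model
#'
#' Fills \code{mobile} for each respondent from a Bernoulli draw with
#' \deqn{P = expit(b_0 + \gamma 4(p-0.5)^2 + \delta\,married\,4(p-0.5)^2 +
#' x'\beta + u_{site}),} where \eqn{p} is the site's true rainfall percentile
#' and \eqn{u_{site}} are seeded site-level normal intercepts.
#'
#' @param dgp a \code{\link{dgp_spec}}.
#' @param respondents respondent data frame (needs \code{site_id},
#'   \code{married}, \code{urban} and the other covariate columns).
#' @param true_percentiles named numeric vector mapping site_id to the true
#'   rainfall percentile in \code{[0, 1]}.
#' @return The respondent data frame with a \code{mobile} column added.
#' @export
simulate_outcome <- function(dgp, respondents, true_percentiles) {
  stopifnot(inherits(dgp, "dgp_spec"))
  miss <- setdiff(unique(respondents$site_id), names(true_percentiles))
  if (length(miss)) {
    stop("no true percentile for site(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  p <- unname(true_percentiles[respondents$site_id])
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("true percentiles must lie in [0, 1]")
  }
  site_ids <- sort(unique(respondents$site_id))
  u_site <- with_seed(substream_seed(dgp$seed, "site_intercepts"), {
    stats::setNames(stats::rnorm(length(site_ids), 0, dgp$site_sd), site_ids)
  })
  s <- ushape_score(p)
  lp <- dgp$baseline_logit + dgp$ushape_gamma * s +
    dgp$interaction_delta * respondents$married * s +
    dgp_covariate_linpred(dgp, respondents) +
    unname(u_site[respondents$site_id])
  respondents$mobile <- with_seed(substream_seed(dgp$seed, "outcome"), {
    stats::rbinom(nrow(respondents), 1, expit(lp))
  })
  respondents
}

#' Monte-Carlo oracle for the true marginal risk ratio
#'
#' Computes the ground-truth marginal risk ratio implied by a generating
#' process: the mean event probability over the supplied respondents with the
#' exposure percentile forced to \code{p_cmp}, divided by the same with
#' exposure forced to \code{p_ref}. Site-level random intercepts are
#' integrated out by Monte Carlo with \code{n_mc} seeded normal draws (with
#' \code{site_sd = 0} the result is exact up to covariate averaging).
#'
#' @param dgp a \code{\link{dgp_spec}}.
#' @param respondents respondent data frame with covariates.
#' @param p_cmp,p_ref exposure percentiles of the contrast, in \code{[0, 1]}.
#' @param n_mc number of Monte-Carlo draws for the random-intercept integral.
#' @return The true marginal risk ratio (a single number).
#' @export
true_marginal_rr <- function(dgp, respondents, p_cmp, p_ref, n_mc = 400) {
  stopifnot(inherits(dgp, "dgp_spec"))
  if (n_mc < 1) stop("n_mc must be >= 1")
  if (p_cmp < 0 || p_cmp > 1 || p_ref < 0 || p_ref > 1) {
    stop("contrast percentiles must lie in [0, 1]")
  }
  lp0 <- dgp$baseline_logit + dgp_covariate_linpred(dgp, respondents)
  married <- respondents$married
  b <- if (dgp$site_sd > 0) {
    with_seed(substream_seed(dgp$seed, "true_rr"),
              stats::rnorm(n_mc, 0, dgp$site_sd))
  } else 0
  mean_prob <- function(p) {
    s <- ushape_score(p)
    lp <- lp0 + dgp$ushape_gamma * s + dgp$interaction_delta * married * s
    mean(vapply(b, function(bm) mean(expit(lp + bm)), numeric(1)))
  }
  mean_prob(p_cmp) / mean_prob(p_ref)
}

#' Simulate a complete analysis-ready study (fast path, no rainfall grid)
#'
#' Convenience wrapper for simulation studies: generates the survey, draws one
#' true exposure percentile per site uniformly on \code{[0, 1]} (the
#' stationary-climate distribution of the empirical percentile), draws
#' outcomes, and returns a single analysis-ready data frame. For the full
#' pipeline through gridded rainfall and the exposure module, see
#' \code{\link{run_pipeline}}.
#'
#' @param dgp a \code{\link{dgp_spec}}.
#' @return A data frame with one row per respondent: survey covariates plus
#'   \code{country}, \code{urban}, \code{percentile} (the true site
#'   percentile) and \code{mobile}. The site table is attached as attribute
#'   \code{"sites"}.
#' @export
simulate_study <- function(dgp) {
  sv <- simulate_survey(dgp, grid = NULL)
  p_site <- with_seed(substream_seed(dgp$seed, "percentiles"), {
    stats::setNames(stats::runif(nrow(sv$sites)), sv$sites$site_id)
  })
  resp <- sv$respondents
  resp$country <- sv$sites$country[match(resp$site_id, sv$sites$site_id)]
  resp$urban <- sv$sites$urban[match(resp$site_id, sv$sites$site_id)]
  resp <- simulate_outcome(dgp, resp, p_site)
  resp$percentile <- unname(p_site[resp$site_id])
  attr(resp, "sites") <- sv$sites
  resp
}
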