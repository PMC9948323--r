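#' Validate pipeline inputs and apply the complete-case rule
#'
#' Reports (and filters) respondents with missing covariates or outcome,
#' sites falling outside the rainfall grid's bounding box, and respondents
#' whose interview date does not leave a complete 30-year rainfall lookback.
#' Analysis uses complete cases only; nothing is imputed.
#'
#' @param sites site data frame.
#' @param respondents respondent data frame.
#' @param grid optional \code{\link{rain_grid}} (geographic checks are
#'   skipped when absent).
#' @return A list: \code{respondents} (clean rows), \code{sites} (covered
#'   sites), \code{dropped} (data frame of dropped respondent ids and
#'   reasons), \code{n_dropped}.
#' @export
validate_inputs <- function(sites, respondents, grid = NULL) {
  covar_cols <- intersect(
    c("age", "wealth_q", "hh_size_cat", "education", "literate", "married",
      "gender", "interview_date", "site_id", "mobile"),
    names(respondents)
  )
  reasons <- rep(NA_character_, nrow(respondents))
  inc <- is.na(reasons)
  for (cc in covar_cols) {
    miss <- inc & is.na(respondents[[cc]])
    reasons[miss] <- paste("missing", cc)
    inc <- is.na(reasons)
  }

  sites_ok <- sites
  if (!is.null(grid)) {
    covered <- sites$lon >= min(grid$lon) & sites$lon <= max(grid$lon) &
      sites$lat >= min(grid$lat) & sites$lat <= max(grid$lat)
    sites_ok <- sites[covered, , drop = FALSE]
    orphan <- inc & !(respondents$site_id %in% sites_ok$site_id)
    reasons[orphan] <- "site not covered by grid"
    inc <- is.na(reasons)

    anchor <- as.Date(respondents$interview_date)
    no_hist <- inc & (shift_years(anchor, -29L) - 365L < min(grid$dates) |
                        anchor - 1L > max(grid$dates))
    reasons[no_hist] <- "insufficient 30-year lookback"
    inc <- is.na(reasons)
  }

  dropped <- data.frame(
    resp_id = respondents$resp_id[!inc],
    reason = reasons[!inc],
    stringsAsFactors = FALSE
  )
  list(
    respondents = respondents[inc, , drop = FALSE],
    sites = sites_ok,
    dropped = dropped,
    n_dropped = nrow(dropped)
  )
}

#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by
#' \code{\link{run_pipeline}}; override any entry (or supply the same
#' structure from a YAML file). A configuration fully determines a run.
#'
#' @param seed master seed.
#' @return A named list of configuration blocks.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    dgp = list(n_countries = 2, sites_per_country = 30,
               respondents_per_site = 100),
    grid = list(n_years = 31, n_cells_x = 8, n_cells_y = 8,
                seasonal_amplitude = 0.8, annual_mean_mm = 900,
                interannual_cv = 0.25, daily_cv = 1),
    exposure = list(method = "nearest", convention = "pooled"),
    model = list(knots = "aic", knot_candidates = c(3, 4, 5)),
    margins = list(ci = "delta",
                   contrasts = list(drought = c(0.15, 0.5),
                                    heavy_rain = c(0.85, 0.5))),
    out_dir = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; entries override \code{\link{default_config}}.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(user$seed)) user$seed else 1)
  for (blk in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
      for (nm in names(user[[blk]])) cfg[[blk]][[nm]] <- user[[blk]][[nm]]
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  if (!is.null(cfg$margins$contrasts)) {
    cfg$margins$contrasts <- lapply(cfg$margins$contrasts, as.numeric)
  }
  cfg
}

## Stable hash of the configuration payload (md5 of its canonical JSON).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic rainfall-mobility pipeline
#'
#' End-to-end reproducible run: simulate the rainfall grid, place the survey,
#' compute the empirical-percentile exposure through the gridded rainfall,
#' draw outcomes from the generating model using those percentiles as truth,
#' validate/complete-case filter, fit the spline logistic model per gender,
#' and compute all marginal contrasts and effect-modification tests. All
#' randomness derives from \code{config$seed}; the same configuration yields
#' an identical report payload.
#'
#' @param config configuration list (see \code{\link{default_config}}) or a
#'   path to a YAML file.
#' @return A report list: \code{payload} (deterministic results: provenance,
#'   descriptives, marginal results, interaction tests, curves) and
#'   \code{generated_at} (timestamp, outside the hashed payload). When
#'   \code{config$out_dir} is set, the exposure table, analysis data set,
#'   results table and report JSON are also written there.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dgp <- do.call(dgp_spec, c(list(seed = config$seed), config$dgp))
  grid <- do.call(simulate_rain_grid,
                  c(list(seed = config$seed), config$grid))

  sv <- simulate_survey(dgp, grid)
  val <- validate_inputs(sv$sites, sv$respondents, grid)

  exposure <- build_exposure_table(grid, val$sites, val$respondents,
                                   method = config$exposure$method,
                                   convention = config$exposure$convention)
  ## site-level truth: all respondents at a site share the interview date,
  ## so the site's computed percentile is the generating percentile
  p_site <- stats::setNames(exposure$percentile, exposure$site_id)
  resp <- val$respondents
  resp$country <- val$sites$country[match(resp$site_id, val$sites$site_id)]
  resp$urban <- val$sites$urban[match(resp$site_id, val$sites$site_id)]
  resp <- simulate_outcome(dgp, resp, p_site)
  resp <- attach_exposure(resp, exposure)

  margins <- stratified_margins(
    resp,
    contrasts = config$margins$contrasts,
    knots = config$model$knots,
    ci = config$margins$ci
  )
  curves <- lapply(margins$fits, function(f) marginal_curve(f))

  payload <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("rainmob")),
      seed = config$seed,
      config_hash = config_hash(config[setdiff(names(config), "out_dir")])
    ),
    descriptives = list(
      n_sites = nrow(val$sites),
      n_respondents = nrow(resp),
      n_dropped = val$n_dropped,
      outcome_prevalence = mean(resp$mobile),
      mean_percentile = mean(exposure$percentile),
      sd_percentile = stats::sd(exposure$percentile)
    ),
    results = margins$results,
    interaction = lapply(margins$interaction, function(t) {
      list(wald_stat = t$wald_stat, df = t$df, p_value = t$p_value)
    }),
    skipped = margins$skipped,
    curves = curves
  )
  report <- list(payload = payload,
                 generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(exposure, file.path(config$out_dir, "exposure.csv"),
                     row.names = FALSE)
    utils::write.csv(resp, file.path(config$out_dir, "analysis_data.csv"),
                     row.names = FALSE)
    utils::write.csv(margins$results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    for (g in names(curves)) {
      utils::write.csv(curves[[g]],
                       file.path(config$out_dir, sprintf("curve_%s.csv", g)),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
  }
  report
}

#' Serialize a fitted model to JSON
#'
#' Writes the named coefficient vector, the clustered covariance as nested
#' arrays, AIC, log-likelihood, knot locations and sample sizes.
#'
#' @param fit a \code{\link{fit_mobility}} result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "logit_fit"))
  jsonlite::write_json(
    list(
      coef = as.list(fit$coef),
      vcov_clustered = unname(apply(fit$vcov_clustered, 1, as.list)),
      coef_names = names(fit$coef),
      loglik = fit$loglik, aic = fit$aic,
      n_obs = fit$n_obs, n_clusters = fit$n_clusters,
      knots = fit$design$knots, cr = fit$cr
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
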