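#' Marginally standardized probability at a counterfactual percentile
#'
#' Implements marginal standardization (g-computation): every respondent's
#' exposure is set to percentile \code{p} (spline and interaction columns
#' re-evaluated, all other covariates left as observed), the fitted model
#' predicts each counterfactual probability, and the predictions are
#' averaged.
#'
#' @param fit a \code{\link{fit_mobility}} result.
#' @param p counterfactual exposure percentile in \code{[0, 1]}.
#' @param subset optional row indices (or logical vector) restricting the
#'   standardization population, e.g. to married respondents.
#' @param strict if \code{TRUE}, a counterfactual percentile outside the
#'   observed exposure support is an error; the default warns (the spline is
#'   linear in its tails, so such contrasts are extrapolations).
#' @return The marginal probability (a single number in (0, 1)).
#' @export
marginal_probability <- function(fit, p, subset = NULL, strict = FALSE) {
  stopifnot(inherits(fit, "logit_fit"))
  if (length(p) != 1 || p < 0 || p > 1) stop("p must be a single value in [0, 1]")
  rng <- fit$design$exposure_range
  if (!is.null(rng) && (p < rng[1] || p > rng[2])) {
    msg <- sprintf("percentile %.3f lies outside the fitted exposure support [%.3f, %.3f]",
                   p, rng[1], rng[2])
    if (strict) stop(msg) else warning(msg)
  }
  X <- design_at_percentile(fit$design, p)
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  if (!nrow(X)) stop("empty standardization population")
  mean(expit(drop(X %*% fit$coef)))
}

## Gradient of the marginal probability w.r.t. the coefficient vector.
.marginal_prob_grad <- function(fit, p, subset = NULL) {
  X <- design_at_percentile(fit$design, p)
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  mu <- expit(drop(X %*% fit$coef))
  list(prob = mean(mu), grad = colMeans(X * (mu * (1 - mu))))
}

#' Marginal risk ratio between two exposure percentiles
#'
#' Ratio of marginally standardized probabilities at \code{p_cmp} versus
#' \code{p_ref} (defaults follow the drought and heavy-rain convention:
#' 0.15 or 0.85 against the median 0.50). Confidence intervals use either the
#' delta method on \eqn{\log RR} — the gradient of the log ratio propagated
#' through the cluster-robust covariance — or a seeded cluster bootstrap
#' (sites resampled with replacement, model refit, percentile interval).
#'
#' @param fit a \code{\link{fit_mobility}} result.
#' @param p_cmp,p_ref exposure percentiles of the contrast.
#' @param ci \code{"delta"} or \code{"bootstrap"}.
#' @param level confidence level.
#' @param subset optional standardization subpopulation (row indices).
#' @param B bootstrap replicates (cluster resamples).
#' @param boot_seed seed for the bootstrap resampling.
#' @param stratum optional label carried into the result.
#' @return An object of class \code{marginal_rr}: the two probabilities, the
#'   risk ratio, the standard error of \eqn{\log RR}, and the confidence
#'   interval.
#' @export
marginal_rr <- function(fit, p_cmp = 0.15, p_ref = 0.5,
                        ci = c("delta", "bootstrap"), level = 0.95,
                        subset = NULL, B = 500, boot_seed = 1,
                        stratum = NA_character_) {
  ci <- match.arg(ci)
  gc_ <- .marginal_prob_grad(fit, p_cmp, subset)
  gr_ <- .marginal_prob_grad(fit, p_ref, subset)
  if (gr_$prob <= .Machine$double.eps) stop("degenerate reference probability")
  rr <- gc_$prob / gr_$prob
  za <- stats::qnorm(1 - (1 - level) / 2)

  if (p_cmp == p_ref) {
    se <- 0; lo <- rr; hi <- rr
  } else if (ci == "delta") {
    g <- gc_$grad / gc_$prob - gr_$grad / gr_$prob
    se <- sqrt(drop(t(g) %*% fit$vcov_clustered %*% g))
    lo <- rr * exp(-za * se); hi <- rr * exp(za * se)
  } else {
    rr_b <- .cluster_bootstrap_rr(fit, p_cmp, p_ref, subset, B, boot_seed)
    se <- stats::sd(log(rr_b))
    qs <- stats::quantile(rr_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(
    list(p_cmp = p_cmp, p_ref = p_ref,
         prob_cmp = gc_$prob, prob_ref = gr_$prob,
         rr = rr, se_log_rr = se, ci_low = lo, ci_high = hi,
         level = level, ci_method = ci, stratum = stratum),
    class = "marginal_rr"
  )
}

#' @export
print.marginal_rr <- function(x, ...) {
  cat(sprintf(
    "marginal RR (p = %.2f vs %.2f)%s: %.3f [%.3f, %.3f] (%s, %g%%)\n",
    x$p_cmp, x$p_ref,
    if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
    x$rr, x$ci_low, x$ci_high, x$ci_method, 100 * x$level
  ))
  invisible(x)
}

## Cluster bootstrap: resample sites with replacement, refit with the same
## knot set, recompute the marginal RR. Non-converging resamples are dropped.
.cluster_bootstrap_rr <- function(fit, p_cmp, p_ref, subset, B, boot_seed) {
  cl <- fit$cluster
  ucl <- unique(cl)
  rows_by_cl <- split(seq_along(cl), cl)[ucl]
  keep <- if (is.null(subset)) rep(TRUE, length(cl)) else {
    k <- rep(FALSE, length(cl)); k[subset] <- TRUE; k
  }
  with_seed(boot_seed, {
    rr_b <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      pick <- sample(length(ucl), replace = TRUE)
      rows <- unlist(rows_by_cl[pick], use.names = FALSE)
      new_cl <- rep(seq_along(pick),
                    times = lengths(rows_by_cl[pick]))
      fb <- tryCatch(
        fit_logistic(fit$design$X[rows, , drop = FALSE], fit$y[rows],
                     new_cl, cr = fit$cr),
        error = function(e) NULL
      )
      if (is.null(fb)) next
      fb$design <- list(
        X = fit$design$X[rows, , drop = FALSE],
        spline_cols = fit$design$spline_cols,
        interaction_cols = fit$design$interaction_cols,
        knots = fit$design$knots,
        married = fit$design$married[rows]
      )
      sub_b <- if (is.null(subset)) NULL else which(keep[rows])
      pc <- marginal_probability(fb, p_cmp, sub_b)
      pr <- marginal_probability(fb, p_ref, sub_b)
      rr_b[b] <- pc / pr
    }
    rr_b[!is.na(rr_b)]
  })
}

#' Joint Wald test for effect modification by marital status
#'
#' Tests whether the married-by-spline interaction coefficients are jointly
#' zero: \eqn{W = \beta_{int}' V_{int}^{-1} \beta_{int}} using the clustered
#' covariance sub-block, referred to a chi-square distribution with one
#' degree of freedom per interaction column. Effect modification is declared
#' at p < 0.05.
#'
#' @param fit a \code{\link{fit_mobility}} result fitted with
#'   \code{interaction = TRUE}.
#' @return An object of class \code{interaction_test}: \code{wald_stat},
#'   \code{df}, \code{p_value}, \code{decision}.
#' @export
interaction_test <- function(fit) {
  stopifnot(inherits(fit, "logit_fit"))
  idx <- fit$design$interaction_cols
  if (!length(idx)) stop("fit has no married x spline interaction terms")
  b <- fit$coef[idx]
  V <- fit$vcov_clustered[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(V), error = function(e) {
    stop("interaction covariance sub-block is singular", call. = FALSE)
  })
  ## with V = R'R, the quadratic form b' V^-1 b is ||R'^-1 b||^2
  w <- drop(crossprod(forwardsolve(t(ch), b)))
  df <- length(idx)
  p <- stats::pchisq(w, df = df, lower.tail = FALSE)
  structure(
    list(wald_stat = w, df = df, p_value = p, decision = p < 0.05),
    class = "interaction_test"
  )
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "joint Wald test for effect modification: chi2(%d) = %.3f, p = %.4g%s\n",
    x$df, x$wald_stat, x$p_value,
    if (x$decision) " (effect modification at 0.05)" else ""
  ))
  invisible(x)
}

#' Marginal probability curve over an exposure grid
#'
#' @param fit a \code{\link{fit_mobility}} result.
#' @param p_grid percentile grid in \code{[0, 1]}; the default covers the
#'   fitted exposure support in steps of 0.02.
#' @param subset optional standardization subpopulation.
#' @return Data frame with columns \code{p} and \code{probability}.
#' @export
marginal_curve <- function(fit, p_grid = NULL, subset = NULL) {
  if (is.null(p_grid)) {
    rng <- fit$design$exposure_range
    if (is.null(rng)) rng <- c(0.02, 0.98)
    p_grid <- seq(max(0.02, rng[1]), min(0.98, rng[2]), by = 0.02)
  }
  if (!length(p_grid)) stop("empty percentile grid")
  if (any(p_grid < 0 | p_grid > 1)) stop("grid must lie in [0, 1]")
  data.frame(
    p = p_grid,
    probability = vapply(p_grid, function(p) marginal_probability(fit, p, subset),
                         numeric(1))
  )
}

#' Stratified marginal risk ratios and effect-modification tests
#'
#' Runs the full contrast battery: per-gender fits (always fully separate, one
#' model per gender), overall drought (0.15 vs 0.50) and heavy-rain (0.85 vs
#' 0.50) contrasts from the no-interaction model, marital-status-specific
#' contrasts evaluated from the single interaction model (standardizing over
#' married and unmarried respondents separately, keeping the joint
#' effect-modification test coherent with the stratum estimates), and
#' optionally per-country refits. Strata that fail preconditions (fewer than
#' two site clusters or only one outcome class) are skipped with a recorded
#' reason, never silently dropped.
#'
#' @param data analysis data frame (see \code{\link{fit_mobility}}).
#' @param genders genders to analyse.
#' @param by_married include marital-status-stratified contrasts and the
#'   joint interaction test.
#' @param by_country also refit per country (country fixed effects drop out
#'   within a single country).
#' @param contrasts named list of \code{c(p_cmp, p_ref)} pairs.
#' @param knots,ci,cr passed through to \code{\link{fit_mobility}} /
#'   \code{\link{marginal_rr}}.
#' @param stratified_fits if \code{TRUE}, marital-status contrasts come from
#'   plain per-group refits instead of the interaction model (sensitivity
#'   cross-check).
#' @return A list: \code{results} (data frame of all contrasts),
#'   \code{interaction} (named list of \code{\link{interaction_test}}s per
#'   gender), \code{skipped} (character vector of skipped strata with
#'   reasons), \code{fits} (the per-gender fitted models).
#' @export
stratified_margins <- function(data, genders = c("woman", "man"),
                               by_married = TRUE, by_country = FALSE,
                               contrasts = list(drought = c(0.15, 0.5),
                                                heavy_rain = c(0.85, 0.5)),
                               knots = "aic", ci = "delta", cr = "CR1",
                               stratified_fits = FALSE) {
  rows <- list()
  tests <- list()
  fits <- list()
  skipped <- character(0)

  viable <- function(d) {
    if (length(unique(d$site_id)) < 2) return("fewer than 2 site clusters")
    if (length(unique(d$mobile)) < 2) return("only one outcome class")
    NULL
  }
  add_row <- function(gender, married, country, name, mr) {
    rows[[length(rows) + 1]] <<- data.frame(
      gender = gender, married = married, country = country, contrast = name,
      p_cmp = mr$p_cmp, p_ref = mr$p_ref, prob_cmp = mr$prob_cmp,
      prob_ref = mr$prob_ref, rr = mr$rr, se_log_rr = mr$se_log_rr,
      ci_low = mr$ci_low, ci_high = mr$ci_high, stringsAsFactors = FALSE
    )
  }

  for (g in genders) {
    dg <- data[data$gender == g, , drop = FALSE]
    why <- if (!nrow(dg)) "no respondents" else viable(dg)
    if (!is.null(why)) {
      skipped <- c(skipped, sprintf("gender=%s: %s", g, why))
      next
    }
    fit_main <- fit_mobility(dg, knots = knots, interaction = FALSE, cr = cr)
    fits[[g]] <- fit_main
    for (nm in names(contrasts)) {
      add_row(g, NA, NA_character_, nm,
              marginal_rr(fit_main, contrasts[[nm]][1], contrasts[[nm]][2],
                          ci = ci, stratum = g))
    }

    if (by_married) {
      fit_int <- fit_mobility(dg, knots = knots, interaction = TRUE, cr = cr)
      tests[[g]] <- interaction_test(fit_int)
      for (m in c(1, 0)) {
        lab <- sprintf("%s/%s", g, if (m == 1) "married" else "unmarried")
        dm <- dg[dg$married == m, , drop = FALSE]
        why <- if (!nrow(dm)) "no respondents" else viable(dm)
        if (!is.null(why)) {
          skipped <- c(skipped, sprintf("%s: %s", lab, why))
          next
        }
        if (stratified_fits) {
          fit_m <- fit_mobility(dm, knots = knots, interaction = FALSE, cr = cr)
          for (nm in names(contrasts)) {
            add_row(g, m, NA_character_, nm,
                    marginal_rr(fit_m, contrasts[[nm]][1], contrasts[[nm]][2],
                                ci = ci, stratum = lab))
          }
        } else {
          sub <- which(dg$married == m)
          for (nm in names(contrasts)) {
            add_row(g, m, NA_character_, nm,
                    marginal_rr(fit_int, contrasts[[nm]][1], contrasts[[nm]][2],
                                ci = ci, subset = sub, stratum = lab))
          }
        }
      }
    }

    if (by_country) {
      for (co in sort(unique(dg$country))) {
        dc <- dg[dg$country == co, , drop = FALSE]
        lab <- sprintf("%s/%s", g, co)
        why <- viable(dc)
        if (!is.null(why)) {
          skipped <- c(skipped, sprintf("%s: %s", lab, why))
          next
        }
        fit_c <- tryCatch(
          fit_mobility(dc, knots = knots, interaction = FALSE, cr = cr),
          error = function(e) conditionMessage(e)
        )
        if (is.character(fit_c)) {
          skipped <- c(skipped, sprintf("%s: %s", lab, fit_c))
          next
        }
        for (nm in names(contrasts)) {
          add_row(g, NA, co, nm,
                  marginal_rr(fit_c, contrasts[[nm]][1], contrasts[[nm]][2],
                              ci = ci, stratum = lab))
        }
      }
    }
  }
  list(results = do.call(rbind, rows), interaction = tests,
       skipped = skipped, fits = fits)
}
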