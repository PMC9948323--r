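#' Logistic maximum likelihood with cluster-robust sandwich variance
#'
#' Fits a binary logistic regression by iteratively reweighted least squares
#' (Newton scoring with step-halving), iterating until the score vector's
#' max-abs norm falls below \code{tol}. The reported covariance is the
#' clustered sandwich estimator: bread = inverse Fisher information, meat =
#' sum over clusters of within-cluster score-sum outer products, scaled by
#' \eqn{G/(G-1)} for \eqn{G} clusters under the default CR1 small-sample
#' correction (CR0 omits the scaling). With every observation its own
#' cluster this reduces to the HC0 heteroskedasticity-robust matrix times the
#' finite-cluster factor.
#'
#' @param X numeric design matrix (full column rank, including intercept).
#' @param y 0/1 outcome vector.
#' @param cluster cluster identifiers (one per row); standard errors are
#'   robust to arbitrary within-cluster correlation.
#' @param cr small-sample correction, \code{"CR1"} (default) or \code{"CR0"}.
#' @param tol convergence tolerance on the max-abs score.
#' @param maxit maximum IRLS iterations.
#' @return An object of class \code{logit_fit}: \code{coef},
#'   \code{vcov_clustered}, \code{vcov_naive} (inverse information),
#'   \code{loglik}, \code{aic}, \code{n_obs}, \code{n_clusters},
#'   \code{gradient_norm}, \code{loglik_trace}, \code{fitted}.
#' @export
fit_logistic <- function(X, y, cluster, cr = c("CR1", "CR0"),
                         tol = 1e-8, maxit = 100L) {
  cr <- match.arg(cr)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (length(cluster) != n) stop("every row needs a cluster id")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: only one class present (perfect separation)")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  loglik_fun <- function(eta) {
    ## sum(y*eta - log(1 + exp(eta))), overflow-safe
    sum(y * eta) - sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
  }

  beta <- numeric(p)
  eta <- drop(X %*% beta)
  ll <- loglik_fun(eta)
  trace <- ll
  for (it in seq_len(maxit)) {
    mu <- expit(eta)
    g <- crossprod(X, y - mu)
    gnorm <- max(abs(g))
    if (gnorm < tol) break
    w <- mu * (1 - mu)
    if (all(w < 1e-12)) stop("perfect separation: all fitted probabilities degenerate")
    H <- crossprod(X * sqrt(w))
    ch <- tryCatch(chol(H), error = function(e) {
      stop("information matrix singular (possible separation)", call. = FALSE)
    })
    delta <- backsolve(ch, forwardsolve(t(ch), g))
    ## step-halving guarantees a non-decreasing log-likelihood
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- drop(X %*% beta_new)
      ll_new <- loglik_fun(eta_new)
      if (ll_new >= ll - 1e-10 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    trace <- c(trace, ll)
    if (max(abs(beta)) > 50) {
      stop("diverging coefficients: possible perfect separation")
    }
  }
  mu <- expit(eta)
  g <- crossprod(X, y - mu)
  gnorm <- max(abs(g))
  if (gnorm >= tol) stop("IRLS failed to reach gradient tolerance")
  if (all(abs(y - mu) < 1e-3)) {
    ## every observation classified perfectly: complete separation satisfies
    ## the gradient criterion with saturated linear predictors. Isolated
    ## saturated cells (an empty dummy category in a small stratum) are
    ## tolerated, as in standard GLM practice.
    stop("perfect separation: fitted probabilities numerically degenerate")
  }

  w <- mu * (1 - mu)
  H <- crossprod(X * sqrt(w))
  bread <- chol2inv(chol(H))
  scores <- X * (y - mu)
  S <- rowsum(scores, group = as.character(cluster))
  G <- nrow(S)
  meat <- crossprod(S)
  adj <- if (cr == "CR1") G / (G - 1) else 1
  V <- bread %*% (adj * meat) %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  dimnames(bread) <- dimnames(V)

  structure(
    list(
      coef = stats::setNames(drop(beta), colnames(X)),
      vcov_clustered = V, vcov_naive = bread,
      loglik = ll, aic = 2 * p - 2 * ll,
      n_obs = n, n_clusters = G, cr = cr,
      gradient_norm = gnorm, loglik_trace = trace,
      fitted = as.numeric(mu)
    ),
    class = "logit_fit"
  )
}

## Fit the mobility design for one candidate knot vector. Covariate columns
## that are constant in the analysis stratum (e.g. `married` in a
## marital-status-stratified refit) are inestimable and dropped, with their
## names recorded on the returned fit.
.fit_candidate <- function(data, knots, include_interaction, cr) {
  design <- build_design(data, knots, include_interaction)
  X <- design$X
  const <- vapply(seq_len(ncol(X)), function(j) all(X[, j] == X[1, j]),
                  logical(1))
  const[1] <- FALSE
  if (any(const)) {
    keep <- which(!const)
    remap <- match(seq_len(ncol(X)), keep)
    if (anyNA(remap[design$spline_cols])) {
      stop("exposure percentile is constant in this stratum")
    }
    design$dropped <- colnames(X)[const]
    design$X <- X[, keep, drop = FALSE]
    design$spline_cols <- remap[design$spline_cols]
    design$interaction_cols <-
      remap[design$interaction_cols][!is.na(remap[design$interaction_cols])]
  }
  fit <- fit_logistic(design$X, data$mobile, data$site_id, cr = cr)
  fit$design <- design
  fit
}

#' Select the number of spline knots by AIC
#'
#' Fits the full mobility model once per candidate knot count (knots at the
#' conventional quantiles of the observed exposure, see
#' \code{\link{place_knots}}) and returns the candidate with the smallest
#' AIC; exact ties go to the model with fewer knots.
#'
#' @param data analysis data frame (see \code{\link{fit_mobility}}).
#' @param candidates integer vector of knot counts to compare.
#' @param include_interaction include married-by-spline interactions during
#'   selection.
#' @param cr sandwich correction passed to \code{\link{fit_logistic}}.
#' @return A list: \code{knots} (chosen locations), \code{k} (chosen count),
#'   \code{aic} (named vector over candidates), \code{fit} (the winning
#'   fitted candidate).
#' @export
select_knots <- function(data, candidates = c(3, 4, 5),
                         include_interaction = FALSE, cr = "CR1") {
  candidates <- sort(unique(as.integer(candidates)))
  fits <- vector("list", length(candidates))
  aic <- rep(NA_real_, length(candidates))
  errs <- character(0)
  for (i in seq_along(candidates)) {
    kn <- place_knots(data$percentile, candidates[i])
    fits[[i]] <- tryCatch(.fit_candidate(data, kn, include_interaction, cr),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      errs <- c(errs, sprintf("%d knots: %s", candidates[i],
                              conditionMessage(fits[[i]])))
    } else {
      aic[i] <- fits[[i]]$aic
    }
  }
  if (all(is.na(aic))) {
    stop("no candidate knot count converged:\n", paste(errs, collapse = "\n"))
  }
  ## ties (to numerical precision) resolved toward fewer knots: candidates are
  ## in ascending order, take the first within tolerance of the minimum
  best <- which(aic <= min(aic, na.rm = TRUE) + 1e-9)[1]
  list(knots = fits[[best]]$design$knots, k = candidates[best],
       aic = stats::setNames(aic, paste0(candidates, "_knots")),
       fit = fits[[best]])
}

#' Fit the rainfall-mobility spline logistic model
#'
#' The package's central fitting function. Models the log-odds of short-term
#' mobility as a restricted cubic spline in the rainfall percentile deviation,
#' adjusted for age, wealth quintile, household size, education, literacy,
#' urban residence, marital status, country fixed effects and survey-month
#' indicators, with standard errors clustered at the site (enumeration-area)
#' level. Models are intended to be fit separately by gender, mirroring
#' standard practice for gendered mobility outcomes.
#'
#' @param data analysis data frame: one row per respondent with the outcome
#'   \code{mobile}, the exposure \code{percentile}, covariates (\code{age},
#'   \code{wealth_q}, \code{hh_size_cat}, \code{education}, \code{literate},
#'   \code{urban}, \code{married}), \code{country}, \code{interview_date},
#'   \code{site_id}, and (if \code{gender} is used) \code{gender}.
#' @param gender optional: \code{"woman"} or \code{"man"} restricts the fit to
#'   that stratum (fully separate fits, never a pooled interaction).
#' @param knots \code{"aic"} (default) selects the knot count from
#'   \code{knot_candidates} by AIC; an integer gives a fixed count at
#'   conventional quantiles; a numeric vector of length >= 3 gives explicit
#'   locations.
#' @param knot_candidates candidate counts for AIC selection.
#' @param interaction include married-by-spline interaction terms (needed for
#'   the effect-modification test and marital-status-stratified contrasts).
#' @param cr cluster-robust small-sample correction (\code{"CR1"}/\code{"CR0"}).
#' @return An object of class \code{mobility_fit} (extending
#'   \code{logit_fit}) with the fitted coefficients, clustered covariance,
#'   AIC, knot set and design metadata.
#' @examples
#' dat <- simulate_study(dgp_spec(seed = 7, n_countries = 2,
#'   sites_per_country = 15, respondents_per_site = 40))
#' fit <- fit_mobility(dat, gender = "woman", knots = 3)
#' fit
#' @export
fit_mobility <- function(data, gender = NULL, knots = "aic",
                         knot_candidates = c(3, 4, 5), interaction = FALSE,
                         cr = "CR1") {
  if (!is.null(gender)) {
    if (!gender %in% c("woman", "man")) stop("gender must be 'woman' or 'man'")
    data <- data[data$gender == gender, , drop = FALSE]
    if (!nrow(data)) stop("no respondents in the requested gender stratum")
  }
  if (!"mobile" %in% names(data)) stop("data must contain the outcome 'mobile'")

  aic_table <- NULL
  if (identical(knots, "aic")) {
    sel <- select_knots(data, knot_candidates, include_interaction = interaction,
                        cr = cr)
    fit <- sel$fit
    aic_table <- sel$aic
  } else if (is.numeric(knots) && length(knots) == 1) {
    fit <- .fit_candidate(data, place_knots(data$percentile, knots),
                          interaction, cr)
  } else if (is.numeric(knots) && length(knots) >= 3) {
    fit <- .fit_candidate(data, knots, interaction, cr)
  } else {
    stop("knots must be \"aic\", a knot count, or a vector of locations")
  }

  fit$y <- as.numeric(data$mobile)
  fit$cluster <- as.character(data$site_id)
  fit$gender <- gender
  fit$interaction <- interaction
  fit$aic_table <- aic_table
  fit$call <- match.call()
  class(fit) <- c("mobility_fit", "logit_fit")
  fit
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat("Rainfall-mobility spline logistic model\n")
  if (!is.null(x$gender)) cat(sprintf("  stratum: %s\n", x$gender))
  cat(sprintf("  n = %d respondents in %d site clusters\n", x$n_obs, x$n_clusters))
  cat(sprintf("  knots (%d): %s\n", length(x$design$knots),
              paste(sprintf("%.3f", x$design$knots), collapse = ", ")))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, %s clustered SEs\n",
              x$loglik, x$aic, x$cr))
  if (x$interaction) cat("  includes married x spline interaction terms\n")
  cat("\nCoefficients (exposure terms):\n")
  idx <- c(x$design$spline_cols, x$design$interaction_cols)
  print(round(x$coef[idx], 4))
  invisible(x)
}

#' @export
summary.mobility_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_clustered))
  z <- object$coef / se
  tab <- cbind(
    Estimate = object$coef, `Robust SE` = se, z = z,
    `Pr(>|z|)` = 2 * stats::pnorm(-abs(z))
  )
  out <- list(coefficients = tab, aic = object$aic, loglik = object$loglik,
              n_obs = object$n_obs, n_clusters = object$n_clusters,
              knots = object$design$knots, gender = object$gender)
  class(out) <- "summary.mobility_fit"
  out
}

#' @export
print.summary.mobility_fit <- function(x, ...) {
  cat(sprintf("Mobility model%s: n = %d, clusters = %d, AIC = %.2f\n",
              if (is.null(x$gender)) "" else paste0(" (", x$gender, ")"),
              x$n_obs, x$n_clusters, x$aic))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.mobility_fit <- function(object, ...) object$coef

#' Covariance matrix of a fitted mobility model
#'
#' @param object a \code{mobility_fit}.
#' @param type \code{"clustered"} (site-level sandwich, default) or
#'   \code{"naive"} (inverse Fisher information).
#' @param ... unused.
#' @export
vcov.mobility_fit <- function(object, type = c("clustered", "naive"), ...) {
  switch(match.arg(type),
         clustered = object$vcov_clustered,
         naive = object$vcov_naive)
}

#' Marginal predicted probability at counterfactual percentiles
#'
#' \code{predict} on a \code{mobility_fit} evaluates the marginally
#' standardized probability at each requested exposure percentile; see
#' \code{\link{marginal_probability}}.
#'
#' @param object a \code{mobility_fit}.
#' @param p numeric vector of exposure percentiles.
#' @param ... unused.
#' @export
predict.mobility_fit <- function(object, p = c(0.15, 0.5, 0.85), ...) {
  vapply(p, function(pi) marginal_probability(object, pi), numeric(1))
}

#' Plot the marginal probability curve of a fitted model
#'
#' @param x a \code{mobility_fit}.
#' @param p_grid percentile grid for the curve (default: the fitted exposure
#'   support).
#' @param ... passed to \code{plot}.
#' @export
plot.mobility_fit <- function(x, p_grid = NULL, ...) {
  cur <- marginal_curve(x, p_grid)
  graphics::plot(cur$p, cur$probability, type = "l",
                 xlab = "rainfall percentile deviation",
                 ylab = "marginal probability of short-term mobility", ...)
  graphics::abline(v = c(0.15, 0.5, 0.85), lty = 3, col = "grey60")
  invisible(cur)
}
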