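## Fixed categorical codings for the survey covariates. Reference categories:
## poorest wealth quintile, household size 1-2, no education, alphabetically
## first country, January survey month.
.hh_levels <- c("1-2", "3-4", "5-7", "8+")
.educ_levels <- c("none", "primary", "secondary", "higher")

#' Build the regression design matrix
#'
#' Expands the analysis data into the model's fixed design: intercept,
#' restricted-cubic-spline basis of the rainfall percentile, age, wealth
#' quintile dummies (reference: poorest), household size dummies (reference:
#' 1-2), education dummies (reference: none), literacy, urban, married,
#' country fixed-effect dummies (reference: alphabetically first code), and
#' survey-month dummies for months present in the data (reference: January,
#' or the earliest month present if January is absent). With
#' \code{include_interaction}, married is additionally crossed with every
#' spline column.
#'
#' @param data analysis data frame: one row per respondent with
#'   \code{percentile}, \code{age}, \code{wealth_q}, \code{hh_size_cat},
#'   \code{education}, \code{literate}, \code{urban}, \code{married},
#'   \code{country}, \code{interview_date}, and the outcome \code{mobile}.
#' @param knots spline knot locations (see \code{\link{rcs_basis}}).
#' @param include_interaction add married-by-spline interaction columns.
#' @param levels optional fixed factor levels (as returned in a fit's
#'   \code{design$levels}); supply these when rebuilding a design at
#'   prediction time so unseen categories raise an error instead of silently
#'   re-basing the dummies.
#' @return A list: \code{X} (numeric matrix), \code{spline_cols},
#'   \code{interaction_cols} (column indices), \code{knots}, \code{levels},
#'   \code{married} (the 0/1 vector, needed to re-evaluate interactions).
#' @export
build_design <- function(data, knots, include_interaction = FALSE,
                         levels = NULL) {
  need <- c("percentile", "age", "wealth_q", "hh_size_cat", "education",
            "literate", "urban", "married", "country", "interview_date")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("design data contain missing values")

  month <- as.POSIXlt(as.Date(data$interview_date))$mon + 1L
  if (is.null(levels)) {
    levels <- list(
      country = sort(unique(as.character(data$country))),
      months = sort(unique(month))
    )
  } else {
    bad_c <- setdiff(unique(as.character(data$country)), levels$country)
    bad_m <- setdiff(unique(month), levels$months)
    if (length(bad_c) || length(bad_m)) {
      stop("unseen category level(s) at prediction time: ",
           paste(c(bad_c, paste0("month ", bad_m)), collapse = ", "))
    }
  }
  if (!all(data$hh_size_cat %in% .hh_levels)) stop("invalid hh_size_cat code")
  if (!all(data$education %in% .educ_levels)) stop("invalid education code")
  if (!all(data$wealth_q %in% 1:5)) stop("invalid wealth_q code")

  dummies <- function(x, lev, prefix) {
    lev_use <- lev[-1]
    m <- matrix(0, length(x), length(lev_use),
                dimnames = list(NULL, paste0(prefix, gsub("[^0-9A-Za-z]+", "_", lev_use))))
    for (j in seq_along(lev_use)) m[, j] <- as.numeric(x == lev_use[j])
    m
  }

  spl <- rcs_basis(data$percentile, knots)
  ref_month <- if (1L %in% levels$months) 1L else min(levels$months)
  month_lev <- c(ref_month, setdiff(levels$months, ref_month))
  X <- cbind(
    `(Intercept)` = 1,
    spl,
    age = data$age,
    dummies(data$wealth_q, 1:5, "wealth_q"),
    dummies(data$hh_size_cat, .hh_levels, "hh"),
    dummies(data$education, .educ_levels, "educ_"),
    literate = as.numeric(data$literate),
    urban = as.numeric(data$urban),
    married = as.numeric(data$married),
    if (length(levels$country) > 1)
      dummies(as.character(data$country), levels$country, "country_"),
    if (length(month_lev) > 1)
      dummies(month, month_lev, "month_")
  )
  spline_cols <- 1L + seq_len(ncol(spl))
  interaction_cols <- integer(0)
  if (include_interaction) {
    inter <- spl * as.numeric(data$married)
    colnames(inter) <- paste0("married_x_", colnames(spl))
    interaction_cols <- ncol(X) + seq_len(ncol(inter))
    X <- cbind(X, inter)
  }
  list(X = X, spline_cols = spline_cols, interaction_cols = interaction_cols,
       knots = knots, levels = levels, married = as.numeric(data$married),
       exposure_range = range(data$percentile))
}

## Re-evaluate the exposure-dependent columns of a design at a fixed
## counterfactual percentile p, leaving all other columns as observed.
design_at_percentile <- function(design, p) {
  b <- rcs_basis(p, design$knots)[1, ]
  X <- design$X
  X[, design$spline_cols] <- matrix(b, nrow(X), length(b), byrow = TRUE)
  if (length(design$interaction_cols)) {
    X[, design$interaction_cols] <- outer(design$married, b)
  }
  X
}
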