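#' Restricted cubic spline basis (truncated-power form)
#'
#' Builds the standard restricted ("natural") cubic spline basis for an
#' exposure measured on \code{[0, 1]}. With \eqn{k} knots
#' \eqn{t_1 < \dots < t_k} the basis has \eqn{k - 1} columns: the identity
#' (linear) term plus \eqn{k - 2} nonlinear terms
#' \deqn{B_j(x) = \frac{(x - t_j)_+^3 -
#'   (x - t_{k-1})_+^3 \frac{t_k - t_j}{t_k - t_{k-1}} +
#'   (x - t_k)_+^3 \frac{t_{k-1} - t_j}{t_k - t_{k-1}}}{(t_k - t_1)^2},}
#' which constrains the fitted function to be linear beyond both boundary
#' knots. The \eqn{(t_k - t_1)^2} normalization keeps the nonlinear columns
#' on roughly the scale of \code{x}.
#'
#' @param x numeric vector of exposure percentiles in \code{[0, 1]}.
#' @param knots strictly increasing knot locations (at least 3) inside the
#'   exposure range.
#' @return A numeric matrix with \code{length(knots) - 1} columns named
#'   \code{rcs1}, \code{rcs2}, ...
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3) stop("restricted cubic splines need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (anyNA(x) || any(x < 0 | x > 1)) stop("exposure percentiles must lie in [0, 1]")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1,
              dimnames = list(NULL, paste0("rcs", seq_len(k - 1))))
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  B
}

#' Conventional quantile knot placement
#'
#' Returns knots at the conventional outer/inner quantiles of the observed
#' exposure distribution: 3 knots at the 10/50/90th percentiles, 4 at
#' 5/35/65/95, 5 at 5/27.5/50/72.5/95.
#'
#' @param x observed exposure values.
#' @param k number of knots (3, 4 or 5).
#' @return Numeric vector of knot locations.
#' @export
place_knots <- function(x, k) {
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    stop("supported knot counts are 3, 4 and 5")
  )
  kn <- unname(stats::quantile(x, probs, type = 7, names = FALSE))
  if (any(diff(kn) <= 0)) {
    stop("degenerate knot placement: exposure has too little spread")
  }
  kn
}
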