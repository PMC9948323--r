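#' @keywords internal
"_PACKAGE"

## Inverse logit / logit shorthands used throughout.
expit <- stats::plogis
logit <- stats::qlogis

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomness in a scenario flows from a single master seed; each stage
#' (rain grid, survey, outcomes, bootstrap, ...) draws from its own sub-stream
#' so stages can be regenerated independently without perturbing one another.
#' The derived seed is a deterministic 31-bit hash of the master seed and the
#' stage label.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return An integer seed in \code{[0, 2^31 - 1)}.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(stage)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Shift a Date by a whole number of calendar years, clamping Feb-29 to
## Feb-28 in non-leap target years.
shift_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L + k
  mo <- lt$mon + 1L
  d <- lt$mday
  dim_target <- days_in_month(y, mo)
  d <- pmin(d, dim_target)
  as.Date(sprintf("%04d-%02d-%02d", y, mo, d))
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  out[month == 2L & leap] <- 29L
  out
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
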