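#' @importFrom rlang .data
#' @importFrom stats qbeta qnorm rpois runif rnorm rgeom rbinom glm lm poisson
#'   AIC coef vcov predict residuals pnorm Box.test quantile setNames
#' @importFrom utils head tail
NULL

# Months elapsed between the month of `from` and the month of `to`
# (calendar months, ignores day-of-month).
month_index <- function(to, from) {
  to <- as.POSIXlt(to)
  from <- as.POSIXlt(from)
  12L * (to$year - from$year) + (to$mon - from$mon)
}

# First day of the calendar month containing `date`.
month_floor <- function(date) {
  as.Date(format(date, "%Y-%m-01"))
}

# First day of the following calendar month.
month_ceiling_next <- function(date) {
  d <- as.POSIXlt(month_floor(date))
  d$mon <- d$mon + 1L
  as.Date(d)
}

# Last day of the calendar month containing `date`.
month_end <- function(date) {
  month_ceiling_next(date) - 1L
}

# Sequence of first-of-month dates covering [start, end].
month_seq <- function(start, end) {
  seq(month_floor(start), month_floor(end), by = "month")
}

as_date_checked <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) stop(sprintf("'%s' is not a valid date", what), call. = FALSE)
  d
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` with the global RNG stream left untouched.
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(expr)
}
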