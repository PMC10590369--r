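#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois runif setNames
#' @importFrom utils head read.csv write.csv
#' @importFrom rlang .data
#' @importFrom methods as
NULL

# Internal: stop with a message naming the offending field/value.
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Internal: is x a single non-negative integer-valued number?
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Internal: check a numeric vector is a probability distribution.
check_distribution <- function(p, name = "p", tol = 1e-8) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", name), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < -tol)) {
    stop(sprintf("`%s` has negative or non-finite entries", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.10f)", name, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}

#' ISO-8601 year and week of a calendar date
#'
#' @param date a `Date` vector.
#' @return a data frame with integer columns `year` (ISO week-based year) and
#'   `week` (ISO week number, 1--53).
#' @export
iso_year_week <- function(date) {
  stopifnot(inherits(date, "Date"))
  data.frame(
    year = as.integer(format(date, "%G")),
    week = as.integer(format(date, "%V"))
  )
}

#' Number of ISO weeks in a week-based year
#'
#' Years whose ISO calendar has 53 weeks are those where Dec 28 falls in
#' week 53.
#'
#' @param year integer vector of ISO week-based years.
#' @return integer vector, 52 or 53.
#' @export
iso_weeks_in_year <- function(year) {
  as.integer(format(as.Date(sprintf("%d-12-28", year)), "%V"))
}

# Internal: sequential week index relative to ISO week 1 of `origin_year`.
# Week 1 of origin_year maps to 1; weeks of later ISO years continue the count.
sequential_week <- function(year, week, origin_year) {
  offset <- vapply(year, function(y) {
    if (y <= origin_year) 0L else sum(iso_weeks_in_year(origin_year:(y - 1L)))
  }, integer(1))
  as.integer(offset + week)
}

# Internal: Monday (Date) starting sequential week t (t = 1 is ISO week 1 of
# origin_year).
week_start_date <- function(t, origin_year) {
  jan4 <- as.Date(sprintf("%d-01-04", origin_year)) # always in ISO week 1
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  monday1 + (t - 1L) * 7L
}
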