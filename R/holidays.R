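#' US federal holiday table
#'
#' The 11 US federal holidays with observed-date shifting: fixed-date
#' holidays falling on a Saturday are observed the preceding Friday and
#' on a Sunday the following Monday.  Juneteenth enters the list from
#' 2021, the year it became a federal holiday.
#'
#' @param years Integer vector of calendar years to cover.
#' @return An object of class `cco_holidays`: a list with `dates`
#'   (sorted `Date` vector of observed holiday dates) and `coverage`
#'   (first and last covered year).
#' @seealso [holiday_table()] for a custom list, [is_holiday()].
#' @export
us_holidays <- function(years) {
  years <- sort(unique(as.integer(years)))
  stopifnot(length(years) >= 1L, !anyNA(years))
  dates <- unlist(lapply(years, function(y) {
    fixed <- c(
      .observed(as.Date(sprintf("%d-01-01", y))),   # New Year's Day
      .observed(as.Date(sprintf("%d-07-04", y))),   # Independence Day
      .observed(as.Date(sprintf("%d-11-11", y))),   # Veterans Day
      .observed(as.Date(sprintf("%d-12-25", y)))    # Christmas Day
    )
    floating <- c(
      .nth_weekday(y, 1L, 1L, 3L),    # Martin Luther King Jr. Day
      .nth_weekday(y, 2L, 1L, 3L),    # Washington's Birthday
      .last_weekday(y, 5L, 1L),       # Memorial Day
      .nth_weekday(y, 9L, 1L, 1L),    # Labor Day
      .nth_weekday(y, 10L, 1L, 2L),   # Columbus Day
      .nth_weekday(y, 11L, 4L, 4L)    # Thanksgiving
    )
    june <- if (y >= 2021L) .observed(as.Date(sprintf("%d-06-19", y))) else NULL
    c(fixed, floating, june)
  }))
  out <- list(dates = sort(unique(as.Date(dates, origin = "1970-01-01"))),
              coverage = range(years))
  class(out) <- "cco_holidays"
  out
}

#' Custom holiday table
#'
#' Wraps an explicit list of holiday dates (e.g. read from a file with
#' one ISO date per line) into the table [is_holiday()] expects.  An
#' empty date list with declared coverage is valid: every lookup in the
#' covered years is then `FALSE`.
#'
#' @param dates Vector coercible to `Date` (may be empty).
#' @param coverage_years Years the table is declared to cover; defaults
#'   to the range of years present in `dates`.
#' @return A `cco_holidays` object.
#' @export
holiday_table <- function(dates, coverage_years = NULL) {
  dates <- as.Date(dates)
  if (is.null(coverage_years)) {
    if (length(dates) == 0L) {
      stop("coverage_years must be given for an empty holiday list",
           call. = FALSE)
    }
    coverage_years <- range(as.integer(format(dates, "%Y")))
  }
  out <- list(dates = sort(unique(dates)),
              coverage = range(as.integer(coverage_years)))
  class(out) <- "cco_holidays"
  out
}

#' Test dates for holiday membership
#'
#' @param date Vector coercible to `Date`.
#' @param holidays A `cco_holidays` table covering every queried year.
#' @return Logical vector, `TRUE` where the date is a (observed)
#'   holiday.
#' @export
is_holiday <- function(date, holidays) {
  stopifnot(inherits(holidays, "cco_holidays"))
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  outside <- yr < holidays$coverage[1L] | yr > holidays$coverage[2L]
  if (any(outside, na.rm = TRUE)) {
    stop("dates outside holiday table coverage (",
         holidays$coverage[1L], "-", holidays$coverage[2L], "): ",
         paste(format(date[which(outside)][seq_len(min(5, sum(outside)))]),
               collapse = ", "),
         call. = FALSE)
  }
  date %in% holidays$dates
}

#' @export
print.cco_holidays <- function(x, ...) {
  cat(sprintf("Holiday table: %d dates covering %d-%d\n",
              length(x$dates), x$coverage[1L], x$coverage[2L]))
  invisible(x)
}

# observed-date shift: Saturday -> preceding Friday, Sunday -> following Monday
.observed <- function(d) {
  wd <- as.POSIXlt(d)$wday  # 0 = Sunday, 6 = Saturday
  d + ifelse(wd == 6L, -1L, ifelse(wd == 0L, 1L, 0L))
}

# nth occurrence of a weekday (1 = Monday .. 7 = Sunday) in a month
.nth_weekday <- function(year, month, weekday, n) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  wd1 <- as.integer(format(first, "%u"))
  first + ((weekday - wd1) %% 7L) + 7L * (n - 1L)
}

.last_weekday <- function(year, month, weekday) {
  nxt <- if (month == 12L) as.Date(sprintf("%d-01-01", year + 1L)) else
    as.Date(sprintf("%d-%02d-01", year, month + 1L))
  last <- nxt - 1L
  wdl <- as.integer(format(last, "%u"))
  last - ((wdl - weekday) %% 7L)
}
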