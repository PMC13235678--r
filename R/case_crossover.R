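#' Time-stratified control days for a case day
#'
#' Returns every other date in the same calendar month and year that
#' falls on the same day of the week as `case_date`, in ascending
#' order, with the case day itself excluded.  This is the
#' time-stratified referent scheme: the case day and its controls
#' partition the month's same-weekday dates, which avoids overlap bias
#' and controls for weekday and seasonal patterning by design.
#'
#' Gregorian months contain four or five of any given weekday, so the
#' result always has three or four dates.
#'
#' @param case_date A single date (coercible with `as.Date`).
#' @return A `Date` vector of length 3 or 4, ascending.
#' @examples
#' control_days("2023-07-06")  # the three other Thursdays of July 2023
#' @export
control_days <- function(case_date) {
  d <- as.Date(case_date)
  stopifnot(length(d) == 1L, !is.na(d))
  cand <- d + 7 * (-5:5)
  same_month <- format(cand, "%Y-%m") == format(d, "%Y-%m")
  sort(cand[same_month & cand != d])
}

#' Build time-stratified case-crossover strata
#'
#' One matched stratum per event: the event's date is the case day and
#' all same-weekday dates in the same month and year are its control
#' days.  "Same location" is operationalized as the event's weather
#' grid cell, so every day in a stratum reads exposure from one weather
#' series.  No events are excluded: duplicate events on the same
#' cell-day each condition their own stratum.
#'
#' @param events Data frame with columns `event_id`, `date`, `cell_id`
#'   and optionally `tract_id` (carried through).  `cell_id` must be
#'   resolved for every event (see [nearest_cell()]).
#' @return A long data frame, one row per stratum-day, with columns
#'   `stratum_id`, `event_id`, `role` (`"case"`/`"control"`), `date`,
#'   `cell_id`, `tract_id`, ordered by stratum then date.
#' @export
build_strata <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("event_id", "date", "cell_id") %in% names(events)))
  events$date <- as.Date(events$date)
  bad <- is.na(events$cell_id)
  if (any(bad)) {
    stop("events with unresolved location (cell_id): ",
         paste(events$event_id[bad], collapse = ", "), call. = FALSE)
  }
  n <- nrow(events)
  if (n == 0L) {
    return(data.frame(stratum_id = character(0), event_id = character(0),
                      role = character(0), date = as.Date(character(0)),
                      cell_id = events$cell_id[0],
                      tract_id = if ("tract_id" %in% names(events))
                        events$tract_id[0] else NA[0]))
  }
  tract <- if ("tract_id" %in% names(events)) events$tract_id else rep(NA, n)
  # enumerate candidate offsets +/- 5 weeks for all events at once
  k <- -5:5
  idx <- rep(seq_len(n), times = length(k))
  cand <- events$date[idx] + rep(7 * k, each = n)
  keep <- format(cand, "%Y-%m") == format(events$date[idx], "%Y-%m")
  sid <- sprintf("s%05d", seq_len(n))
  out <- data.frame(
    stratum_id = sid[idx][keep],
    event_id = events$event_id[idx][keep],
    role = ifelse(cand[keep] == events$date[idx][keep], "case", "control"),
    date = cand[keep],
    cell_id = events$cell_id[idx][keep],
    tract_id = tract[idx][keep],
    row.names = NULL
  )
  out[order(out$stratum_id, out$date), , drop = FALSE]
}
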