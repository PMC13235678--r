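#' Nearest weather grid cell by great-circle distance
#'
#' Assigns each point to the grid cell whose centre minimizes the
#' haversine great-circle distance, with deterministic ties broken
#' toward the smallest `cell_id`.
#'
#' @param lon,lat Numeric vectors of point coordinates (decimal
#'   degrees, equal length).
#' @param cells Data frame with columns `cell_id`, `lon`, `lat`.
#' @return Vector of `cell_id`s, one per point.
#' @export
nearest_cell <- function(lon, lat, cells) {
  stopifnot(length(lon) == length(lat))
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    stop("cell set is empty", call. = FALSE)
  }
  stopifnot(all(c("cell_id", "lon", "lat") %in% names(cells)))
  stopifnot(all(lon >= -180 & lon <= 180), all(lat >= -90 & lat <= 90))
  # order cells by id so the first minimum encountered is the tie-break
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  centres <- cbind(cells$lon, cells$lat)
  vapply(seq_along(lon), function(i) {
    d <- geosphere::distHaversine(c(lon[i], lat[i]), centres)
    cells$cell_id[which.min(d)]
  }, cells$cell_id[1L])
}

#' Categorize daily precipitation
#'
#' Three-level rainfall category used as an adjustment covariate:
#' 0 for a dry day, 1 for rainfall below the study-period mean, 2 for
#' rainfall at or above it.  A day exactly at the mean is assigned the
#' wetter category so category 1 is strictly interior.
#'
#' @param precip_mm Daily rainfall in mm (vector, >= 0).
#' @param mean_mm Study-period mean rainfall cut-off in mm (default
#'   2.68).
#' @return Integer vector in `{0, 1, 2}`.
#' @export
precip_category <- function(precip_mm, mean_mm = 2.68) {
  stopifnot(length(mean_mm) == 1L, mean_mm > 0)
  if (any(precip_mm < 0, na.rm = TRUE)) {
    stop("negative precipitation", call. = FALSE)
  }
  ifelse(precip_mm == 0, 0L, ifelse(precip_mm < mean_mm, 1L, 2L))
}

#' Link daily exposures to matched stratum days
#'
#' Joins each stratum-day to its grid cell's weather by cell and date,
#' copying daily maximum and mean temperature exactly, deriving the
#' precipitation category and flagging holidays.  A stratum with
#' weather missing for any of its days is dropped whole, with a
#' warning: a matched set with incomplete exposure cannot contribute to
#' the conditional likelihood.
#'
#' @param strata Long stratum table from [build_strata()].
#' @param weather Weather table with `cell_id`, `date`, `tmax_c`,
#'   `tmean_c`, `precip_mm`.
#' @param holidays A `cco_holidays` table covering the study years
#'   (default: US federal holidays over the years present in `strata`).
#' @param mean_mm Precipitation category cut-off passed to
#'   [precip_category()].
#' @return Data frame of linked stratum-days: `stratum_id`, `date`,
#'   `role`, `cell_id`, `tract_id`, `dtmax_c`, `dtmean_c`, `precip_mm`,
#'   `precip_cat`, `holiday`.
#' @export
link_exposures <- function(strata, weather, holidays = NULL, mean_mm = 2.68) {
  stopifnot(is.data.frame(strata),
            all(c("stratum_id", "role", "date", "cell_id") %in% names(strata)))
  strata$date <- as.Date(strata$date)
  weather$date <- as.Date(weather$date)
  if (is.null(holidays)) {
    yrs <- unique(as.integer(format(strata$date, "%Y")))
    holidays <- us_holidays(yrs)
  }
  idx <- match(paste(strata$cell_id, strata$date),
               paste(weather$cell_id, weather$date))
  miss <- is.na(idx)
  if (any(miss)) {
    dropped <- unique(strata$stratum_id[miss])
    warning(sprintf("dropping %d stratum/strata with missing weather (%d day rows)",
                    length(dropped), sum(miss)), call. = FALSE)
    keep <- !(strata$stratum_id %in% dropped)
    strata <- strata[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  data.frame(
    stratum_id = strata$stratum_id,
    date = strata$date,
    role = strata$role,
    cell_id = strata$cell_id,
    tract_id = if ("tract_id" %in% names(strata)) strata$tract_id else NA,
    dtmax_c = weather$tmax_c[idx],
    dtmean_c = weather$tmean_c[idx],
    precip_mm = weather$precip_mm[idx],
    precip_cat = precip_category(weather$precip_mm[idx], mean_mm),
    holiday = is_holiday(strata$date, holidays),
    row.names = NULL
  )
}
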