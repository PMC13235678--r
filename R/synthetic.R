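#' Configuration for the synthetic study generator
#'
#' Bundles the ground-truth parameters used to simulate the three data
#' sources a temperature case-crossover study needs: a daily gridded
#' weather surface, point events whose daily hazard depends
#' log-linearly on daily maximum temperature, and census-tract tables
#' carrying population counts for deprivation indices.
#'
#' The event model is Bernoulli per cell-day:
#' \deqn{\mathrm{logit}\,P(\text{event}) = \alpha_c +
#'   \beta_T (T^{max}_{cd} - 23.5) + \gamma_H \, 1[\text{holiday}]}
#' where \eqn{\alpha_c} is a cell-specific baseline centred at
#' `qlogis(baseline_rate)`.  A Bernoulli (rather than Poisson) outcome
#' keeps every event day unambiguous for matched-stratum construction,
#' which conditions on one case day per stratum.
#'
#' @param n_cells Number of weather grid cells (>= 1).
#' @param n_tracts Number of census tracts (>= 1).
#' @param date_start,date_end Study window (coercible to `Date`); must
#'   span at least 60 days so month-stratified matching is possible.
#' @param beta_temp True log-odds change per degree C of daily maximum
#'   temperature.
#' @param gamma_holiday True log-odds shift on US federal holidays.
#' @param baseline_rate Expected event probability per cell-day at the
#'   referent temperature (23.5 degrees C) on a non-holiday; in (0, 1).
#' @param seasonal_amplitude Amplitude (degrees C) of the annual
#'   sinusoid, peaking July 15.
#' @param noise_sd Day-to-day weather noise SD (degrees C, >= 0).
#' @param precip_zero_prob Probability a cell-day is dry.
#' @param precip_mean_wet Mean (mm) of the exponential draw on wet
#'   days.  The default gives an overall precipitation mean of
#'   2.68 mm at the default dry-day probability.
#' @param cell_sd SD of the cell-level baseline log-odds deviations.
#' @param referent Temperature (degrees C) at which `baseline_rate`
#'   applies; defaults to the median daily maximum of 23.5.
#' @param seed Integer seed; identical configurations and seeds
#'   reproduce every table byte for byte.
#'
#' @return An object of class `cco_config` (a validated list).
#' @seealso [generate_weather()], [generate_events()],
#'   [generate_tracts()], [write_synthetic_data()]
#' @export
synthetic_config <- function(n_cells = 15L,
                             n_tracts = 50L,
                             date_start = "2013-01-01",
                             date_end = "2014-12-31",
                             beta_temp = 0.006,
                             gamma_holiday = 0.1,
                             baseline_rate = 0.08,
                             seasonal_amplitude = 12,
                             noise_sd = 3,
                             precip_zero_prob = 0.6,
                             precip_mean_wet = 2.68 / 0.4,
                             cell_sd = 0.3,
                             referent = 23.5,
                             seed = 20130101L) {
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  stopifnot(
    length(n_cells) == 1L, n_cells >= 1,
    length(n_tracts) == 1L, n_tracts >= 1,
    !is.na(date_start), !is.na(date_end),
    is.finite(beta_temp), is.finite(gamma_holiday),
    baseline_rate > 0, baseline_rate < 1,
    noise_sd >= 0, seasonal_amplitude >= 0,
    precip_zero_prob >= 0, precip_zero_prob <= 1,
    precip_mean_wet > 0, cell_sd >= 0,
    is.finite(referent),
    length(seed) == 1L, is.finite(seed)
  )
  if (date_start >= date_end) {
    stop("`date_start` must precede `date_end`", call. = FALSE)
  }
  cfg <- list(
    n_cells = as.integer(n_cells), n_tracts = as.integer(n_tracts),
    date_start = date_start, date_end = date_end,
    beta_temp = beta_temp, gamma_holiday = gamma_holiday,
    baseline_rate = baseline_rate,
    seasonal_amplitude = seasonal_amplitude, noise_sd = noise_sd,
    precip_zero_prob = precip_zero_prob,
    precip_mean_wet = precip_mean_wet,
    cell_sd = cell_sd, referent = referent, seed = as.integer(seed)
  )
  class(cfg) <- "cco_config"
  cfg
}

#' @export
print.cco_config <- function(x, ...) {
  cat("Synthetic case-crossover study configuration\n")
  cat(sprintf("  %d grid cells, %d tracts, %s to %s\n",
              x$n_cells, x$n_tracts, x$date_start, x$date_end))
  cat(sprintf("  beta_temp = %g per degree C, gamma_holiday = %g, baseline_rate = %g\n",
              x$beta_temp, x$gamma_holiday, x$baseline_rate))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

## Seed offsets keep the three generators independently reproducible
## while still driven by one user-facing seed; the large prime offsets
## avoid stream collisions between nearby user seeds (e.g. replicate
## batches run at consecutive seeds).
.seed_weather <- function(cfg) set.seed(cfg$seed %% 2147480000L)
.seed_events  <- function(cfg) set.seed((cfg$seed + 104729L) %% 2147480000L)
.seed_tracts  <- function(cfg) set.seed((cfg$seed + 224737L) %% 2147480000L)

#' Simulate a daily gridded weather surface
#'
#' One series per grid cell over every date in the configured window.
#' Daily maximum temperature is a cell-specific mean plus an annual
#' sinusoid peaking July 15 plus Gaussian noise; daily mean temperature
#' is the maximum minus a fixed 8 degree C offset; precipitation is zero
#' with probability `precip_zero_prob` and exponential otherwise.
#'
#' @param config A [synthetic_config()].
#' @return A data frame with columns `cell_id`, `date`, `tmax_c`,
#'   `tmean_c`, `precip_mm`, ordered by cell then date.  The cell
#'   metadata (centre coordinates, cell mean temperature, fixed tract
#'   assignment) is attached as attribute `"cells"` and retrievable
#'   with [weather_cells()].
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "cco_config"))
  dates <- seq(config$date_start, config$date_end, by = "day")
  if (length(dates) < 60L) {
    stop("date range must cover at least 60 days for month-stratified matching",
         call. = FALSE)
  }
  .seed_weather(config)
  n <- config$n_cells
  cells <- data.frame(
    cell_id = seq_len(n),
    lon = stats::runif(n, -120, -75),
    lat = stats::runif(n, 30, 45),
    mean_tmax_c = stats::runif(n, 10, 20),
    tract_id = sample.int(config$n_tracts, n, replace = TRUE)
  )
  doy <- as.POSIXlt(dates)$yday + 1L
  seasonal <- config$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  nd <- length(dates)
  tmax <- rep(cells$mean_tmax_c, each = nd) +
    rep(seasonal, times = n) +
    stats::rnorm(n * nd, 0, config$noise_sd)
  dry <- stats::runif(n * nd) < config$precip_zero_prob
  precip <- ifelse(dry, 0, stats::rexp(n * nd, 1 / config$precip_mean_wet))
  weather <- data.frame(
    cell_id = rep(cells$cell_id, each = nd),
    date = rep(dates, times = n),
    tmax_c = tmax,
    tmean_c = tmax - 8,
    precip_mm = precip
  )
  attr(weather, "cells") <- cells
  weather
}

#' Grid-cell metadata of a simulated weather table
#'
#' @param weather Output of [generate_weather()].
#' @return Data frame with `cell_id`, `lon`, `lat`, `mean_tmax_c`,
#'   `tract_id`.
#' @export
weather_cells <- function(weather) {
  cells <- attr(weather, "cells")
  if (is.null(cells)) stop("no cell metadata attached to this weather table",
                           call. = FALSE)
  cells
}

#' Simulate events from a weather surface
#'
#' Each cell-day experiences an event as an independent Bernoulli draw
#' whose log-odds are the cell baseline plus
#' `beta_temp * (tmax - referent)` plus `gamma_holiday` on US federal
#' holidays.  Each event is placed at its generating cell's centre and
#' inherits the cell's fixed tract assignment.
#'
#' @param config A [synthetic_config()].
#' @param weather Output of [generate_weather()] for the same config.
#' @return Data frame of events (`event_id`, `date`, `lon`, `lat`,
#'   `cell_id`, `tract_id`) with the generating parameters attached as
#'   attribute `"truth"`; see [ground_truth()].
#' @export
generate_events <- function(config, weather) {
  stopifnot(inherits(config, "cco_config"))
  cells <- weather_cells(weather)
  dates <- seq(config$date_start, config$date_end, by = "day")
  if (!all(dates %in% weather$date[weather$cell_id == cells$cell_id[1L]])) {
    stop("weather table does not cover the configured date range", call. = FALSE)
  }
  .seed_events(config)
  alpha <- stats::qlogis(config$baseline_rate) +
    stats::rnorm(config$n_cells, 0, config$cell_sd)
  yrs <- seq(as.integer(format(config$date_start, "%Y")),
             as.integer(format(config$date_end, "%Y")))
  hol <- us_holidays(yrs)
  hflag <- weather$date %in% hol$dates
  eta <- alpha[match(weather$cell_id, cells$cell_id)] +
    config$beta_temp * (weather$tmax_c - config$referent) +
    config$gamma_holiday * hflag
  hit <- stats::runif(nrow(weather)) < stats::plogis(eta)
  ev <- weather[hit, c("cell_id", "date")]
  idx <- match(ev$cell_id, cells$cell_id)
  events <- data.frame(
    event_id = if (nrow(ev)) sprintf("ev%05d", seq_len(nrow(ev))) else character(0),
    date = ev$date,
    lon = cells$lon[idx],
    lat = cells$lat[idx],
    cell_id = ev$cell_id,
    tract_id = cells$tract_id[idx],
    row.names = NULL
  )
  attr(events, "truth") <- list(
    beta_temp = config$beta_temp,
    gamma_holiday = config$gamma_holiday,
    baseline_log_odds = stats::setNames(alpha, cells$cell_id),
    referent = config$referent,
    seed = config$seed
  )
  events
}

#' Ground-truth parameters of a simulated event table
#'
#' @param events Output of [generate_events()].
#' @return List with `beta_temp`, `gamma_holiday`, per-cell
#'   `baseline_log_odds`, `referent` and `seed`.
#' @export
ground_truth <- function(events) {
  truth <- attr(events, "truth")
  if (is.null(truth)) stop("no ground truth attached to this event table",
                           call. = FALSE)
  truth
}

#' Simulate census-tract population tables
#'
#' Generates `n_tracts` records with a total population and, for each
#' of the four deprivation dimensions (income, racialized income,
#' homeownership, education), counts of persons at the privileged and
#' deprived extremes.  Extremes are constructed so the resulting Index
#' of Concentration at the Extremes spans strongly negative through
#' strongly positive values, guaranteeing all three national terciles
#' are populated once `n_tracts` is moderately large.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `tract_id`, `pop_total`, and
#'   `<dimension>_privileged` / `<dimension>_deprived` count columns for
#'   each of the four dimensions.
#' @export
generate_tracts <- function(config) {
  stopifnot(inherits(config, "cco_config"))
  .seed_tracts(config)
  n <- config$n_tracts
  pop <- round(stats::runif(n, 1200, 8000))
  out <- data.frame(tract_id = seq_len(n), pop_total = pop)
  for (dim in ice_dimensions()) {
    # target polarization spread across the full range, share of the
    # population classified at either extreme between 50% and 95%
    u <- stats::runif(n, -0.9, 0.9)
    s <- stats::runif(n, 0.5, 0.95)
    priv <- floor(pop * s * (1 + u) / 2)
    depr <- floor(pop * s * (1 - u) / 2)
    out[[paste0(dim, "_privileged")]] <- priv
    out[[paste0(dim, "_deprived")]] <- depr
  }
  out
}

#' Write a complete synthetic study to disk
#'
#' Emits `events.csv`, `weather.csv`, `tracts.csv` and `truth.json`
#' into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the three tables and the ground
#'   truth.
#' @export
write_synthetic_data <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  weather <- generate_weather(config)
  events <- generate_events(config, weather)
  tracts <- generate_tracts(config)
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(weather, file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(weather_cells(weather), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tracts, file.path(dir, "tracts.csv"), row.names = FALSE)
  truth <- ground_truth(events)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(events = events, weather = weather, tracts = tracts,
                 truth = truth))
}
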