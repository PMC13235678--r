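#' Deprivation dimensions measured by the Index of Concentration at
#' the Extremes
#'
#' @return Character vector of the four dimension names used
#'   throughout: overall income, racialized income, homeownership and
#'   educational attainment.
#' @export
ice_dimensions <- function() {
  c("income", "race_income", "homeownership", "education")
}

#' Index of Concentration at the Extremes
#'
#' ICE = (A - P) / T, where A and P count persons at the privileged
#' and deprived extremes of a dimension and T is the tract population
#' whose privilege level was measured.  Values run from -1 (everyone at
#' the deprived extreme) to +1 (everyone at the privileged extreme).
#'
#' @param privileged,deprived,total Non-negative counts (vectors
#'   recycled to a common length); `privileged + deprived <= total` and
#'   `total > 0`.
#' @return Numeric vector in `[-1, 1]`.
#' @export
ice_value <- function(privileged, deprived, total) {
  if (any(total <= 0, na.rm = TRUE)) {
    stop("ICE undefined for non-positive total population", call. = FALSE)
  }
  if (any(privileged < 0 | deprived < 0, na.rm = TRUE)) {
    stop("extreme-group counts must be non-negative", call. = FALSE)
  }
  if (any(privileged + deprived > total, na.rm = TRUE)) {
    stop("privileged + deprived exceeds total population", call. = FALSE)
  }
  (privileged - deprived) / total
}

#' Compute ICE values for a tract table
#'
#' @param tracts Data frame with `tract_id`, `pop_total` and, for each
#'   requested dimension, `<dim>_privileged` and `<dim>_deprived`
#'   columns.
#' @param dimensions Dimensions to compute (default all four).
#' @return `tracts` with an added `ice_<dim>` column per dimension.
#' @export
compute_ice <- function(tracts, dimensions = ice_dimensions()) {
  stopifnot(is.data.frame(tracts),
            all(c("tract_id", "pop_total") %in% names(tracts)))
  for (dim in dimensions) {
    a <- tracts[[paste0(dim, "_privileged")]]
    p <- tracts[[paste0(dim, "_deprived")]]
    if (is.null(a) || is.null(p)) {
      stop("missing count columns for dimension: ", dim, call. = FALSE)
    }
    tracts[[paste0("ice_", dim)]] <- ice_value(a, p, tracts$pop_total)
  }
  tracts
}

#' National tercile cut-points of an ICE distribution
#'
#' Empirical 33.33% and 66.67% quantiles of the unweighted tract-level
#' distribution, computed by linear interpolation of order statistics
#' (R quantile type 7).  Tracts, not persons, are the unit: the
#' national tract-level distribution defines the cut-points.
#'
#' @param values Numeric vector of ICE values (>= 3 finite values).
#' @return Numeric length-2 vector `(q13, q23)`.
#' @export
tercile_cutpoints <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop("need at least 3 finite values to define terciles", call. = FALSE)
  }
  unname(stats::quantile(values, probs = c(1, 2) / 3, type = 7))
}

#' Assign tracts to national terciles
#'
#' Tercile 1 holds the most deprived (lowest-ICE) tracts and tercile 3
#' the most privileged.  Boundaries are lower-closed: a value exactly
#' at a cut-point goes to the lower (more deprived) tercile.
#'
#' @param ice Numeric vector of finite ICE values.
#' @param cutpoints Length-2 vector from [tercile_cutpoints()].
#' @return Integer vector in `{1, 2, 3}`.
#' @export
assign_tercile <- function(ice, cutpoints) {
  stopifnot(length(cutpoints) == 2L, all(is.finite(ice)))
  ifelse(ice <= cutpoints[1L], 1L, ifelse(ice <= cutpoints[2L], 2L, 3L))
}

#' Case counts and incidence rates by deprivation tercile
#'
#' Assigns every tract to a national tercile of the chosen dimension,
#' then pools cases and population within tercile.  The rate is the
#' pooled incidence, `100000 * sum(cases) / sum(population)` — one rate
#' per tercile, stable to very small tracts.
#'
#' @param events Data frame of cases with a `tract_id` column.
#' @param tracts Tract table; `ice_<dimension>` is computed on the fly
#'   if absent.
#' @param dimension One of [ice_dimensions()].
#' @return Data frame with one row per tercile: `dimension`, `tercile`,
#'   `n_tracts`, `cases`, `population`, `rate_per_100k`.
#' @export
tercile_rates <- function(events, tracts, dimension = "income") {
  stopifnot(dimension %in% ice_dimensions() ||
              paste0("ice_", dimension) %in% names(tracts))
  icecol <- paste0("ice_", dimension)
  if (!icecol %in% names(tracts)) tracts <- compute_ice(tracts, dimension)
  unknown <- !(events$tract_id %in% tracts$tract_id)
  if (any(unknown)) {
    stop("events with unknown tract_id: ",
         paste(unique(events$tract_id[unknown]), collapse = ", "),
         call. = FALSE)
  }
  cp <- tercile_cutpoints(tracts[[icecol]])
  terc <- assign_tercile(tracts[[icecol]], cp)
  case_terc <- terc[match(events$tract_id, tracts$tract_id)]
  out <- data.frame(
    dimension = dimension,
    tercile = 1:3,
    n_tracts = as.integer(tabulate(terc, 3L)),
    cases = as.integer(tabulate(case_terc, 3L)),
    population = vapply(1:3, function(k)
      sum(tracts$pop_total[terc == k]), numeric(1))
  )
  out$rate_per_100k <- ifelse(out$population > 0,
                              1e5 * out$cases / out$population, 0)
  out
}
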