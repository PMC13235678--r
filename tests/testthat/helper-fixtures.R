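# Shared fixtures and independent oracles for the test suite.

# A small but complete synthetic study: weather + events + strata + linked.
small_study <- function(seed = 101L, n_cells = 6L,
                        date_start = "2013-01-01", date_end = "2013-12-31",
                        ...) {
  cfg <- synthetic_config(n_cells = n_cells, date_start = date_start,
                          date_end = date_end, seed = seed, ...)
  weather <- generate_weather(cfg)
  events <- generate_events(cfg, weather)
  strata <- build_strata(events)
  linked <- link_exposures(strata, weather)
  list(cfg = cfg, weather = weather, events = events, strata = strata,
       linked = linked)
}

# Random small matched dataset for likelihood tests: n_strata strata of
# one case plus `m` controls, `p` design columns; case chosen by the
# conditional model itself so the data are generated under the
# likelihood being tested.
random_matched_design <- function(seed, n_strata = 8L, m = 3L, p = 1L,
                                  beta = rep(0.5, p)) {
  set.seed(seed)
  rows <- (m + 1L) * n_strata
  X <- matrix(rnorm(rows * p), ncol = p)
  stratum <- rep(seq_len(n_strata), each = m + 1L)
  case <- logical(rows)
  for (s in seq_len(n_strata)) {
    idx <- which(stratum == s)
    eta <- X[idx, , drop = FALSE] %*% beta
    pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
    case[sample(idx, 1L, prob = pr)] <- TRUE
  }
  list(X = X, stratum = stratum, case = case)
}

# Brute-force maximizer of the conditional log-likelihood by iterative
# grid refinement; independent of the Newton path under test.
grid_search_loglik <- function(X, stratum, case, lower = -5, upper = 5,
                               n_grid = 21L, rounds = 8L) {
  p <- ncol(X)
  lo <- rep(lower, p); hi <- rep(upper, p)
  best <- rep(0, p)
  best_ll <- -Inf
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j],
                                                length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    lls <- apply(pts, 1L, function(b)
      conditional_loglik(b, X, stratum, case)$loglik)
    k <- which.max(lls)
    if (lls[k] > best_ll) { best_ll <- lls[k]; best <- pts[k, ] }
    span <- (hi - lo) / (n_grid - 1L)
    lo <- best - span; hi <- best + span
  }
  list(beta = best, loglik = best_ll)
}

# Calendar-scan oracle for the time-stratified referent scheme:
# enumerate every day of the case month and keep same-weekday days.
calendar_scan_controls <- function(d) {
  d <- as.Date(d)
  first <- as.Date(format(d, "%Y-%m-01"))
  month_days <- seq(first, by = "day", length.out = 31L)
  month_days <- month_days[format(month_days, "%m") == format(d, "%m")]
  same <- month_days[weekdays(month_days) == weekdays(d)]
  same[same != d]
}

# Plain haversine, written against the textbook formula (radius 6378137
# m, matching the default geodesic sphere radius of the implementation
# under test only through the *ordering* of distances, which is all the
# nearest-cell contract needs).
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6371000) {
  torad <- pi / 180
  dlat <- (lat2 - lat1) * torad
  dlon <- (lon2 - lon1) * torad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * torad) * cos(lat2 * torad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Truncated-power natural cubic spline basis (independent construction
# for the basis-equivalence oracle).  Natural cubic spline with knots
# k_1 < ... < k_K: basis {x, d_1(x) - d_{K-1}(x), ..., d_{K-2}(x) -
# d_{K-1}(x)} where d_j(x) = ((x - k_j)_+^3 - (x - k_K)_+^3)/(k_K - k_j).
truncated_power_ns <- function(x, knots_all) {
  K <- length(knots_all)
  dd <- function(j) {
    (pmax(x - knots_all[j], 0)^3 - pmax(x - knots_all[K], 0)^3) /
      (knots_all[K] - knots_all[j])
  }
  dK1 <- dd(K - 1L)
  cols <- lapply(seq_len(K - 2L), function(j) dd(j) - dK1)
  cbind(x, do.call(cbind, cols))
}

# One parameter-recovery replicate: simulate, match, link, fit a linear
# holiday-adjusted model; returns the temperature coefficient and SE.
recovery_rep <- function(seed, beta_temp = 0.006, n_cells = 18L,
                         date_start = "2013-01-01",
                         date_end = "2014-12-31", ...) {
  cfg <- synthetic_config(n_cells = n_cells, date_start = date_start,
                          date_end = date_end, beta_temp = beta_temp,
                          seed = seed, ...)
  weather <- generate_weather(cfg)
  events <- generate_events(cfg, weather)
  linked <- link_exposures(build_strata(events), weather)
  fit <- clr_fit(build_design(linked, model_spec(covariates = "holiday")))
  c(beta = unname(fit$beta["dtmax"]),
    se = sqrt(fit$covariance["dtmax", "dtmax"]),
    n_events = nrow(events))
}
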