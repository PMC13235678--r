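#' Exposure percentiles over case days
#'
#' Empirical quantiles (linear interpolation of order statistics) of
#' the exposure distribution over case days, the anchor points at
#' which odds-ratio contrasts are reported.
#'
#' @param linked Output of [link_exposures()].
#' @param probs Probabilities; default the conventional set
#'   `{.05, .10, .25, .50, .75, .90, .95, .99}`.
#' @param exposure `"dtmax"` or `"dtmean"`.
#' @param case_only Use case days only (default) or all stratum days.
#' @param min_n Minimum number of contributing days (default 100).
#' @return Data frame with `prob` and `temp_c`, non-decreasing in
#'   `prob`.
#' @export
exposure_percentiles <- function(linked,
                                 probs = c(.05, .10, .25, .50, .75, .90,
                                           .95, .99),
                                 exposure = c("dtmax", "dtmean"),
                                 case_only = TRUE,
                                 min_n = 100L) {
  exposure <- match.arg(exposure)
  x <- linked[[paste0(exposure, "_c")]]
  if (case_only) x <- x[linked$role == "case"]
  x <- x[is.finite(x)]
  if (length(x) < min_n) {
    stop(sprintf("need at least %d exposure days (have %d)", min_n,
                 length(x)), call. = FALSE)
  }
  data.frame(prob = probs,
             temp_c = unname(stats::quantile(x, probs = probs, type = 7)))
}

#' Odds ratio at a temperature relative to the referent
#'
#' Forms the contrast `c = b(t) - b(ref)` in the fitted exposure basis
#' (zero-padded over covariate columns), so `log OR = c' beta` with
#' delta-method standard error `sqrt(c' Sigma c)` and Wald 95% limits
#' `exp(log OR +/- 1.96 se)`.  At the referent the OR is exactly 1
#' with zero-width interval.
#'
#' @param fit A converged [clr_fit()] carrying its spec (i.e. fitted
#'   via [build_design()]).
#' @param t Temperature(s) in degrees C.
#' @param ref Referent in degrees C; defaults to the fit's referent.
#' @return Data frame with one row per `t`: `temp_c`, `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`.
#' @export
or_at <- function(fit, t, ref = NULL) {
  stopifnot(inherits(fit, "cco_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(fit$spec)) {
    stop("fit carries no model spec; refit via build_design()", call. = FALSE)
  }
  if (is.null(ref)) ref <- fit$spec$referent
  # basis was built on referent-centred exposure
  bt <- eval_basis(fit$basis, t - fit$spec$referent)
  br <- eval_basis(fit$basis, rep(ref - fit$spec$referent, length(t)))
  k <- ncol(bt)
  p <- length(fit$beta)
  C <- cbind(bt - br, matrix(0, nrow = length(t), ncol = p - k))
  log_or <- drop(C %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((C %*% fit$covariance) * C)))
  data.frame(
    temp_c = t,
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci_low = exp(log_or - 1.96 * se),
    ci_high = exp(log_or + 1.96 * se)
  )
}

#' Exposure-response curve on a fine temperature grid
#'
#' @param fit A converged [clr_fit()].
#' @param from,to Grid limits in degrees C.
#' @param by Grid step (default 0.1 degrees C).
#' @param ref Referent; defaults to the fit's referent.
#' @return [or_at()] output over the grid.
#' @export
or_curve <- function(fit, from, to, by = 0.1, ref = NULL) {
  or_at(fit, seq(from, to, by = by), ref = ref)
}

#' Stratified conditional-logistic fits
#'
#' Refits the full model independently on the subsets of matched
#' strata whose case carries each label (e.g. deprivation tercile of
#' the case's census tract, or geographic region).  Labels partition
#' strata, not days: every day of a stratum follows its case's label.
#'
#' @param linked Output of [link_exposures()].
#' @param labels Data frame with `stratum_id` and `label`, or a vector
#'   named by `stratum_id`.
#' @param spec A [model_spec()] applied to every subset.
#' @return List with `fits` (named list of `cco_fit`, one per label
#'   level that fit successfully) and `failed` (named character vector
#'   of error messages for levels that could not be fitted).
#' @export
stratified_fits <- function(linked, labels, spec) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("stratum_id", "label") %in% names(labels)))
    lab <- stats::setNames(labels$label, labels$stratum_id)
  } else {
    lab <- labels
  }
  strat_lab <- lab[as.character(linked$stratum_id)]
  if (anyNA(strat_lab)) {
    stop("strata without a label: ",
         paste(utils::head(unique(linked$stratum_id[is.na(strat_lab)]), 5),
               collapse = ", "), call. = FALSE)
  }
  levels <- sort(unique(lab))
  fits <- list()
  failed <- character(0)
  for (lv in levels) {
    sub <- linked[strat_lab == lv, , drop = FALSE]
    res <- tryCatch(clr_fit(build_design(sub, spec)),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "cco_fit")) {
      fits[[as.character(lv)]] <- res
    } else {
      failed[as.character(lv)] <- res
    }
  }
  list(fits = fits, failed = failed)
}

#' Deprivation-tercile labels for matched strata
#'
#' Assigns each stratum the national ICE tercile of the census tract
#' where its case occurred, for one deprivation dimension.
#'
#' @param linked Output of [link_exposures()] (case rows must carry
#'   `tract_id`).
#' @param tracts Tract table (ICE computed on the fly if absent).
#' @param dimension One of [ice_dimensions()].
#' @return Data frame with `stratum_id` and `label`
#'   (`"tercile1"`..`"tercile3"`).
#' @export
tercile_labels <- function(linked, tracts, dimension = "income") {
  icecol <- paste0("ice_", dimension)
  if (!icecol %in% names(tracts)) tracts <- compute_ice(tracts, dimension)
  cp <- tercile_cutpoints(tracts[[icecol]])
  terc <- assign_tercile(tracts[[icecol]], cp)
  cases <- linked[linked$role == "case", c("stratum_id", "tract_id")]
  idx <- match(cases$tract_id, tracts$tract_id)
  if (anyNA(idx)) {
    stop("case tract_id not found in tract table: ",
         paste(unique(cases$tract_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(stratum_id = cases$stratum_id,
             label = paste0("tercile", terc[idx]))
}

#' Cochran's Q test of cross-stratum heterogeneity
#'
#' Fixed-effect heterogeneity statistic over k independent estimates:
#' with weights `w_i = 1/se_i^2` and precision-weighted pooled mean
#' `theta_bar`, `Q = sum w_i (theta_i - theta_bar)^2`, referred to the
#' upper tail of a chi-square with `k - 1` degrees of freedom.
#'
#' @param estimates Numeric vector of stratum-specific log-ORs at a
#'   fixed contrast (k >= 2).
#' @param ses Matching standard errors, all > 0.
#' @return An object of class `cco_qtest`: `q`, `df`, `p_value`,
#'   `pooled`, `estimates`, `ses`.
#' @export
cochran_q <- function(estimates, ses) {
  k <- length(estimates)
  stopifnot(length(ses) == k)
  if (k < 2L) stop("need at least 2 stratum estimates", call. = FALSE)
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("all standard errors must be positive", call. = FALSE)
  }
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - pooled)^2)
  out <- list(q = q, df = k - 1L,
              p_value = stats::pchisq(q, df = k - 1L, lower.tail = FALSE),
              pooled = pooled, estimates = estimates, ses = ses)
  class(out) <- "cco_qtest"
  out
}

#' @export
print.cco_qtest <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.4f (pooled log-OR %.4f)\n",
              x$q, x$df, x$p_value, x$pooled))
  invisible(x)
}
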