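#' Model specification for a case-crossover fit
#'
#' Declares how exposure enters the conditional logistic model: which
#' daily temperature metric, a linear term or a natural cubic spline
#' with 2-4 degrees of freedom, which adjustment covariates, and the
#' referent temperature at which odds ratios are anchored to 1.
#'
#' @param exposure `"dtmax"` (daily maximum, default) or `"dtmean"`.
#' @param form `"linear"` or `"ns"` (natural cubic spline).
#' @param df Spline degrees of freedom in `{2, 3, 4}`; ignored for the
#'   linear form.
#' @param covariates Subset of `c("holiday", "precip_cat")`.
#' @param referent Referent temperature in degrees C.  Default 23.5
#'   (the median daily maximum); 17.1 is the conventional referent for
#'   daily mean temperature.
#' @return An object of class `cco_model_spec`.
#' @export
model_spec <- function(exposure = c("dtmax", "dtmean"),
                       form = c("linear", "ns"),
                       df = NULL,
                       covariates = character(),
                       referent = NULL) {
  exposure <- match.arg(exposure)
  form <- match.arg(form)
  if (form == "ns") {
    if (is.null(df) || !(df %in% 2:4)) {
      stop("spline df must be 2, 3 or 4", call. = FALSE)
    }
    df <- as.integer(df)
  } else {
    df <- NULL
  }
  stopifnot(all(covariates %in% c("holiday", "precip_cat")))
  if (is.null(referent)) referent <- if (exposure == "dtmax") 23.5 else 17.1
  stopifnot(is.finite(referent))
  out <- list(exposure = exposure, form = form, df = df,
              covariates = covariates, referent = referent)
  class(out) <- "cco_model_spec"
  out
}

#' @export
print.cco_model_spec <- function(x, ...) {
  frm <- if (x$form == "linear") "linear" else sprintf("ns(df = %d)", x$df)
  cat(sprintf("Model spec: %s, %s, referent %.1f C", x$exposure, frm,
              x$referent))
  if (length(x$covariates)) cat(", covariates:",
                                paste(x$covariates, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Natural cubic spline basis for an exposure
#'
#' Boundary knots sit at the observed exposure range and the `df - 1`
#' interior knots at equally spaced quantiles, so the basis is natural
#' (zero second derivative at and beyond the boundaries, hence linear
#' extrapolation).  Built on `splines::ns`.
#'
#' @param values Exposure values the basis is anchored to.
#' @param df Degrees of freedom in `{2, 3, 4}`.
#' @return An object of class `cco_spline_basis` with an evaluation
#'   method [eval_basis()].
#' @export
spline_basis <- function(values, df) {
  stopifnot(df %in% 2:4)
  values <- values[is.finite(values)]
  if (length(unique(values)) < df + 2L) {
    stop("need at least df + 2 distinct exposure values", call. = FALSE)
  }
  boundary <- range(values)
  probs <- seq_len(df - 1L) / df
  knots <- unname(stats::quantile(values, probs = probs, type = 7))
  out <- list(df = as.integer(df), knots = knots, boundary = boundary)
  class(out) <- "cco_spline_basis"
  out
}

#' Evaluate a basis at exposure values
#'
#' For a spline basis returns the `df`-column natural spline design;
#' for the degenerate `NULL` basis (linear exposure) returns the
#' one-column identity.
#'
#' @param basis A `cco_spline_basis` or `NULL` for linear.
#' @param x Numeric exposure values.
#' @return Matrix with one row per value.
#' @export
eval_basis <- function(basis, x) {
  if (is.null(basis)) return(matrix(x, ncol = 1L))
  stopifnot(inherits(basis, "cco_spline_basis"))
  m <- splines::ns(x, knots = basis$knots, Boundary.knots = basis$boundary,
                   intercept = FALSE)
  matrix(as.numeric(m), nrow = length(x))
}

#' Render linked stratum-days to a conditional-logistic design
#'
#' Builds the dense design matrix the likelihood consumes.  The
#' exposure is centred at the referent before basis construction (the
#' conditional likelihood is translation-invariant, so this only
#' improves conditioning); holidays enter as one binary column and
#' precipitation as two dummy columns (categories 1 and 2 versus dry).
#'
#' @param linked Output of [link_exposures()].
#' @param spec A [model_spec()].
#' @return List with `X` (design matrix), `stratum` (integer stratum
#'   index per row), `case` (logical per row), `stratum_id`, `labels`,
#'   `basis` (`NULL` for linear) and `spec`.
#' @export
build_design <- function(linked, spec) {
  stopifnot(inherits(spec, "cco_model_spec"), is.data.frame(linked))
  expocol <- paste0(spec$exposure, "_c")
  stopifnot(expocol %in% names(linked))
  x <- linked[[expocol]] - spec$referent
  if (spec$form == "linear") {
    basis <- NULL
    X <- matrix(x, ncol = 1L)
    labels <- spec$exposure
  } else {
    basis <- spline_basis(x, spec$df)
    X <- eval_basis(basis, x)
    labels <- paste0(spec$exposure, "_ns", seq_len(spec$df))
  }
  if ("holiday" %in% spec$covariates) {
    X <- cbind(X, as.numeric(linked$holiday))
    labels <- c(labels, "holiday")
  }
  if ("precip_cat" %in% spec$covariates) {
    X <- cbind(X, as.numeric(linked$precip_cat == 1L),
               as.numeric(linked$precip_cat == 2L))
    labels <- c(labels, "precip_cat1", "precip_cat2")
  }
  colnames(X) <- labels
  sid <- factor(linked$stratum_id, levels = unique(linked$stratum_id))
  list(X = X, stratum = as.integer(sid), case = linked$role == "case",
       stratum_id = levels(sid), labels = labels, basis = basis, spec = spec)
}

#' Conditional logistic log-likelihood, gradient and Hessian
#'
#' Each matched stratum contributes the log-probability that its case
#' day, among all days in the stratum, carries the event:
#' \deqn{\ell(\beta) = \sum_s \left[\eta_{case,s} -
#'   \log \sum_{j \in s} e^{\eta_j}\right], \quad \eta = X\beta.}
#' Gradient and Hessian are the exact analytic derivatives (score and
#' observed information).  Stratum-wise log-sum-exp is computed with a
#' max shift for numerical stability.
#'
#' @param beta Coefficient vector matching `ncol(X)`.
#' @param X Design matrix, one row per stratum-day.
#' @param stratum Integer stratum index per row.
#' @param case Logical, `TRUE` on the single case row of each stratum.
#' @return List with `loglik`, `gradient` and `hessian` (the Hessian
#'   is negative semi-definite).
#' @export
conditional_loglik <- function(beta, X, stratum, case) {
  stopifnot(length(beta) == ncol(X), nrow(X) == length(stratum),
            length(case) == length(stratum))
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  S <- max(stratum)
  # per-stratum max for a stable log-sum-exp (strata need not be contiguous)
  mx <- as.numeric(tapply(eta, stratum, max))
  w <- exp(eta - mx[stratum])
  denom <- drop(rowsum(w, stratum, reorder = TRUE))
  p <- w / denom[stratum]
  loglik <- sum(eta[case]) - sum(log(denom) + mx)
  gradient <- drop(crossprod(X, case - p))
  Xp <- X * p
  A <- crossprod(X, Xp)
  M <- rowsum(Xp, stratum, reorder = TRUE)
  hessian <- -(A - crossprod(M))
  list(loglik = loglik, gradient = gradient, hessian = hessian)
}

# validate stratum structure; drop strata without controls (warning),
# error on strata without exactly one case row
.validate_strata <- function(X, stratum, case, stratum_id = NULL) {
  ncase <- drop(rowsum(as.numeric(case), stratum, reorder = TRUE))
  nrow_s <- drop(rowsum(rep(1, length(stratum)), stratum, reorder = TRUE))
  if (any(ncase != 1)) {
    stop("each stratum must contain exactly one case row", call. = FALSE)
  }
  no_ctrl <- nrow_s < 2
  if (any(no_ctrl)) {
    warning(sprintf("excluding %d stratum/strata with no control days",
                    sum(no_ctrl)), call. = FALSE)
    keep <- !(stratum %in% which(no_ctrl))
    X <- X[keep, , drop = FALSE]
    case <- case[keep]
    stratum <- as.integer(factor(stratum[keep]))
  }
  list(X = X, stratum = stratum, case = case)
}

#' Fit a conditional logistic regression by Newton-Raphson
#'
#' Maximizes the conditional likelihood of [conditional_loglik()] by
#' guarded Newton iteration: start at `beta = 0`, full Newton step with
#' step-halving (at most 30 halvings) whenever the likelihood would
#' decrease, stop when the likelihood improvement falls below `1e-10`
#' or the gradient sup-norm below `1e-8`, at most 50 iterations.  The
#' conditional log-likelihood is concave, so this is globally
#' convergent away from separation.  The coefficient covariance is the
#' inverse observed information at the optimum.
#'
#' Columns that are constant within every stratum carry no information
#' under the conditional likelihood and are rejected before fitting;
#' any coefficient exceeding 50 in absolute value during iteration is
#' treated as separation (monotone likelihood) and raised as an error
#' naming the offending column.
#'
#' @param design Either the list from [build_design()] or a design
#'   matrix (then `stratum` and `case` are required).
#' @param stratum,case See [conditional_loglik()]; ignored when
#'   `design` is a `build_design()` list.
#' @param labels Optional column labels when calling with a bare
#'   matrix.
#' @return An object of class `cco_fit`: `beta` (named), `covariance`,
#'   `loglik`, `aic`, `n_strata`, `iterations`, `converged`, plus the
#'   spec and basis when fitted from a [build_design()] list.
#' @export
clr_fit <- function(design, stratum = NULL, case = NULL, labels = NULL) {
  if (is.list(design) && !is.data.frame(design) && !is.matrix(design)) {
    X <- design$X; stratum <- design$stratum; case <- design$case
    labels <- design$labels
    spec <- design$spec; basis <- design$basis
  } else {
    X <- as.matrix(design)
    stopifnot(!is.null(stratum), !is.null(case))
    if (is.null(labels)) {
      labels <- colnames(X)
      if (is.null(labels)) labels <- paste0("x", seq_len(ncol(X)))
    }
    spec <- NULL; basis <- NULL
  }
  colnames(X) <- labels
  v <- .validate_strata(X, stratum, case)
  X <- v$X; stratum <- v$stratum; case <- v$case
  S <- max(stratum)
  if (S < 1L) stop("no informative strata", call. = FALSE)
  # identifiability: each column must vary within at least one stratum
  ctr <- X - rowsum(X, stratum, reorder = TRUE)[stratum, , drop = FALSE] /
    drop(rowsum(rep(1, length(stratum)), stratum, reorder = TRUE))[stratum]
  const <- apply(abs(ctr), 2L, max) < 1e-12
  if (any(const)) {
    stop("stratum-constant (non-identifiable) column(s): ",
         paste(labels[const], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  cur <- conditional_loglik(beta, X, stratum, case)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    if (max(abs(cur$gradient)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hessian, cur$gradient), error = function(e)
      stop("singular hessian: conditional information matrix not invertible",
           call. = FALSE))
    lambda <- 1
    for (h in 0:30) {
      cand <- beta + lambda * step
      new <- tryCatch(conditional_loglik(cand, X, stratum, case),
                      error = function(e) NULL)
      if (!is.null(new) && is.finite(new$loglik) &&
          new$loglik >= cur$loglik - 1e-12) break
      lambda <- lambda / 2
    }
    if (any(abs(cand) > 50)) {
      worst <- labels[which.max(abs(cand))]
      stop("separation detected (|beta| > 50) for column: ", worst,
           call. = FALSE)
    }
    improve <- new$loglik - cur$loglik
    beta <- cand
    cur <- new
    if (abs(improve) < 1e-10) { converged <- TRUE; break }
  }
  if (!converged && max(abs(cur$gradient)) < 1e-8) converged <- TRUE
  covariance <- tryCatch(solve(-cur$hessian), error = function(e)
    stop("singular hessian at optimum", call. = FALSE))
  dimnames(covariance) <- list(labels, labels)
  fit <- list(
    beta = stats::setNames(beta, labels),
    covariance = covariance,
    loglik = cur$loglik,
    aic = -2 * cur$loglik + 2 * p,
    n_strata = S,
    iterations = iter,
    converged = converged,
    labels = labels,
    spec = spec,
    basis = basis
  )
  class(fit) <- "cco_fit"
  fit
}

#' @export
print.cco_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit: %d strata, loglik %.4f, AIC %.4f%s\n",
              x$n_strata, x$loglik, x$aic,
              if (x$converged) "" else " (NOT converged)"))
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(coef = x$beta, se = se,
                    z = x$beta / se,
                    `exp(coef)` = exp(x$beta), check.names = FALSE)
  print(round(tab, 5))
  invisible(x)
}

#' Select the exposure parameterization by AIC
#'
#' Fits every candidate specification on the same linked data and
#' returns the converged fit with minimal AIC.  Ties (within `1e-8`)
#' are broken toward fewer parameters, then toward the linear form.
#' Candidates that fail to fit are recorded, not fatal, unless all
#' fail.
#'
#' @param linked Output of [link_exposures()].
#' @param specs List of [model_spec()] candidates (default: linear and
#'   natural splines with 2-4 df on daily maximum temperature).
#' @return List with `best_spec`, `best_fit`, `fits` (one per
#'   candidate, `NULL` where failed), and `table` (form, df, number of
#'   parameters, loglik, AIC, convergence per candidate).
#' @export
select_parameterization <- function(linked, specs = NULL) {
  if (is.null(specs)) {
    specs <- c(list(model_spec(form = "linear")),
               lapply(2:4, function(d) model_spec(form = "ns", df = d)))
  }
  stopifnot(length(specs) >= 1L)
  fits <- lapply(specs, function(sp) {
    tryCatch(clr_fit(build_design(linked, sp)), error = function(e) {
      structure(list(error = conditionMessage(e)), class = "cco_fit_failure")
    })
  })
  ok <- vapply(fits, function(f) inherits(f, "cco_fit") && f$converged,
               logical(1))
  tab <- data.frame(
    exposure = vapply(specs, `[[`, "", "exposure"),
    form = vapply(specs, `[[`, "", "form"),
    df = vapply(specs, function(s) if (is.null(s$df)) NA_integer_ else s$df,
                integer(1)),
    n_par = vapply(fits, function(f)
      if (inherits(f, "cco_fit")) length(f$beta) else NA_integer_, integer(1)),
    loglik = vapply(fits, function(f)
      if (inherits(f, "cco_fit")) f$loglik else NA_real_, numeric(1)),
    aic = vapply(fits, function(f)
      if (inherits(f, "cco_fit")) f$aic else NA_real_, numeric(1)),
    converged = ok
  )
  if (!any(ok)) stop("all candidate parameterizations failed", call. = FALSE)
  aic <- ifelse(ok, tab$aic, Inf)
  npar <- ifelse(ok, tab$n_par, Inf)
  is_lin <- tab$form == "linear"
  best <- order(round(aic / 1e-8) * 1e-8, npar, !is_lin)[1L]
  list(best_spec = specs[[best]], best_fit = fits[[best]],
       fits = fits, table = tab)
}
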