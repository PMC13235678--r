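#' Run configuration for the case-crossover pipeline
#'
#' Assembles and validates the options one end-to-end run needs.
#' Exactly one data source must be given: file paths to event,
#' weather and tract tables, or an inline synthetic configuration.
#'
#' @param paths Named list with `events`, `weather`, `tracts` (CSV
#'   paths; `cells` optional for point-to-cell resolution), or `NULL`.
#' @param synthetic A [synthetic_config()] or a named list of its
#'   arguments, or `NULL`.
#' @param model A [model_spec()]; default linear daily maximum
#'   temperature adjusted for holidays, referent 23.5 C.
#' @param select_aic Compare linear and spline (2-4 df)
#'   parameterizations by AIC before fitting (default `TRUE`).
#' @param percentiles Probabilities for the odds-ratio table.
#' @param mean_mm Precipitation category cut-off (mm).
#' @param holidays_path Optional file of ISO holiday dates (one per
#'   line) overriding the US federal list.
#' @param stratify_dimensions ICE dimensions to stratify over.
#' @param seed Integer seed for the synthetic source.
#' @param outdir Output directory.
#' @return An object of class `cco_run_config`.
#' @export
run_config <- function(paths = NULL,
                       synthetic = NULL,
                       model = model_spec(covariates = "holiday"),
                       select_aic = TRUE,
                       percentiles = c(.05, .10, .25, .50, .75, .90, .95, .99),
                       mean_mm = 2.68,
                       holidays_path = NULL,
                       stratify_dimensions = ice_dimensions(),
                       seed = 20130101L,
                       outdir = tempfile("cco_run_")) {
  if (is.null(paths) == is.null(synthetic)) {
    stop("supply exactly one of `paths` or `synthetic`", call. = FALSE)
  }
  if (!is.null(paths)) {
    stopifnot(all(c("events", "weather", "tracts") %in% names(paths)))
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cco_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synthetic_config, synthetic)
  }
  stopifnot(inherits(model, "cco_model_spec"))
  out <- list(paths = paths, synthetic = synthetic, model = model,
              select_aic = isTRUE(select_aic), percentiles = percentiles,
              mean_mm = mean_mm, holidays_path = holidays_path,
              stratify_dimensions = stratify_dimensions,
              seed = as.integer(seed), outdir = outdir)
  class(out) <- "cco_run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror [run_config()] arguments; the `model` block
#' takes `exposure`, `form`, `df`, `covariates`, `referent`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param seed,outdir Optional overrides of the file's values.
#' @return A `cco_run_config`.
#' @export
read_run_config <- function(path, seed = NULL, outdir = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model <- if (is.null(raw$model)) model_spec(covariates = "holiday") else
    model_spec(exposure = raw$model$exposure %||% "dtmax",
               form = raw$model$form %||% "linear",
               df = raw$model$df,
               covariates = unlist(raw$model$covariates) %||% character(0),
               referent = raw$model$referent)
  run_config(
    paths = raw$paths,
    synthetic = raw$synthetic,
    model = model,
    select_aic = raw$select_aic %||% TRUE,
    percentiles = unlist(raw$percentiles) %||%
      c(.05, .10, .25, .50, .75, .90, .95, .99),
    mean_mm = raw$mean_mm %||% 2.68,
    holidays_path = raw$holidays_path,
    stratify_dimensions = unlist(raw$stratify_dimensions) %||%
      ice_dimensions(),
    seed = seed %||% raw$seed %||% 20130101L,
    outdir = outdir %||% raw$outdir %||% tempfile("cco_run_")
  )
}

.load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    weather <- generate_weather(config$synthetic)
    events <- generate_events(config$synthetic, weather)
    tracts <- generate_tracts(config$synthetic)
    cells <- weather_cells(weather)
  } else {
    events <- utils::read.csv(config$paths$events)
    weather <- utils::read.csv(config$paths$weather)
    tracts <- utils::read.csv(config$paths$tracts)
    cells <- if (!is.null(config$paths$cells)) {
      utils::read.csv(config$paths$cells)
    } else {
      unique(weather[, "cell_id", drop = FALSE])
    }
    events$date <- as.Date(events$date)
    weather$date <- as.Date(weather$date)
    # resolve events lacking a grid cell from coordinates
    if (!"cell_id" %in% names(events) || anyNA(events$cell_id)) {
      if (!all(c("lon", "lat") %in% names(cells))) {
        stop("events lack cell_id and no cell coordinates were supplied",
             call. = FALSE)
      }
      need <- if ("cell_id" %in% names(events)) is.na(events$cell_id) else
        rep(TRUE, nrow(events))
      events$cell_id[need] <- nearest_cell(events$lon[need], events$lat[need],
                                           cells)
    }
  }
  list(events = events, weather = weather, tracts = tracts, cells = cells)
}

#' Run the full case-crossover pipeline
#'
#' Executes generate/load, matched-stratum construction, exposure
#' linkage, (optional) AIC parameterization selection, the conditional
#' logistic fit, percentile odds-ratio extraction, the
#' exposure-response curve, ICE computation with tercile incidence
#' rates, deprivation-stratified fits with Cochran's Q heterogeneity
#' tests, and descriptives.  All interface tables are written as CSV
#' into `config$outdir`, the fit as `fit.json`, and a `run_report.json`
#' with stage timings, in/out counts and the selected parameterization.
#' Identical configurations and seeds reproduce every output.
#'
#' @param config A [run_config()] (or path handled by
#'   [read_run_config()]).
#' @return Invisibly, a list with every intermediate object and the
#'   report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cco_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), warnings = character(0))
  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0, ...) {
    report$stages[[stage]] <<- c(list(seconds = round(tic() - t0, 3)),
                                 list(...))
  }
  withCallingHandlers({
    t0 <- tic()
    inputs <- .load_inputs(config)
    note("load", t0, n_events = nrow(inputs$events),
         n_weather_rows = nrow(inputs$weather),
         n_tracts = nrow(inputs$tracts))
    utils::write.csv(inputs$events, file.path(config$outdir, "events.csv"),
                     row.names = FALSE)

    t0 <- tic()
    strata <- build_strata(inputs$events)
    note("match", t0, n_strata = length(unique(strata$stratum_id)))
    utils::write.csv(strata, file.path(config$outdir, "strata.csv"),
                     row.names = FALSE)

    t0 <- tic()
    holidays <- if (!is.null(config$holidays_path)) {
      holiday_table(readLines(config$holidays_path))
    } else NULL
    linked <- link_exposures(strata, inputs$weather, holidays,
                             config$mean_mm)
    note("link", t0, n_linked_days = nrow(linked),
         n_strata_linked = length(unique(linked$stratum_id)))
    utils::write.csv(linked, file.path(config$outdir, "linked.csv"),
                     row.names = FALSE)

    t0 <- tic()
    if (config$select_aic) {
      forms <- c(list(model_spec(exposure = config$model$exposure,
                                 form = "linear",
                                 covariates = config$model$covariates,
                                 referent = config$model$referent)),
                 lapply(2:4, function(d)
                   model_spec(exposure = config$model$exposure, form = "ns",
                              df = d, covariates = config$model$covariates,
                              referent = config$model$referent)))
      sel <- select_parameterization(linked, forms)
      fit <- sel$best_fit
      spec <- sel$best_spec
      utils::write.csv(sel$table, file.path(config$outdir, "aic_table.csv"),
                       row.names = FALSE)
    } else {
      sel <- NULL
      spec <- config$model
      fit <- clr_fit(build_design(linked, spec))
    }
    note("fit", t0,
         selected_form = if (spec$form == "linear") "linear" else
           sprintf("ns(df=%d)", spec$df),
         aic = fit$aic, loglik = fit$loglik, converged = fit$converged)
    jsonlite::write_json(
      list(labels = fit$labels, beta = as.numeric(fit$beta),
           covariance = unname(as.matrix(fit$covariance)),
           loglik = fit$loglik, aic = fit$aic, n_strata = fit$n_strata,
           iterations = fit$iterations, converged = fit$converged),
      file.path(config$outdir, "fit.json"), auto_unbox = TRUE, digits = NA)

    t0 <- tic()
    pct <- exposure_percentiles(linked, config$percentiles,
                                exposure = spec$exposure,
                                min_n = min(100L, sum(linked$role == "case")))
    or_tab <- cbind(prob = pct$prob, or_at(fit, pct$temp_c))
    rng <- range(linked[[paste0(spec$exposure, "_c")]])
    curve <- or_curve(fit, rng[1], rng[2], by = 0.1)
    note("effects", t0)
    utils::write.csv(or_tab, file.path(config$outdir, "or_table.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(config$outdir, "curve.csv"),
                     row.names = FALSE)

    t0 <- tic()
    tracts_ice <- compute_ice(inputs$tracts)
    utils::write.csv(tracts_ice, file.path(config$outdir, "ice.csv"),
                     row.names = FALSE)
    rates <- do.call(rbind, lapply(config$stratify_dimensions, function(d)
      tercile_rates(inputs$events, tracts_ice, d)))
    utils::write.csv(rates, file.path(config$outdir, "tercile_summary.csv"),
                     row.names = FALSE)
    note("ice", t0)

    t0 <- tic()
    strat_rows <- list(); q_rows <- list()
    hot <- pct$temp_c[which.max(pct$prob)]
    cold <- pct$temp_c[which.min(pct$prob)]
    for (d in config$stratify_dimensions) {
      labs <- tercile_labels(linked, tracts_ice, d)
      sf <- stratified_fits(linked, labs, spec)
      for (side in c("cold", "hot")) {
        contrast <- if (side == "hot") hot else cold
        ors <- lapply(names(sf$fits), function(lv) {
          cbind(dimension = d, label = lv, side = side,
                n_strata = sf$fits[[lv]]$n_strata,
                or_at(sf$fits[[lv]], contrast))
        })
        strat_rows <- c(strat_rows, ors)
        if (length(sf$fits) >= 2L) {
          est <- vapply(sf$fits, function(f) or_at(f, contrast)$log_or,
                        numeric(1))
          se <- vapply(sf$fits, function(f) or_at(f, contrast)$se, numeric(1))
          qt <- cochran_q(est, se)
          q_rows[[paste(d, side)]] <- data.frame(
            dimension = d, side = side, temp_c = contrast, q = qt$q,
            df = qt$df, p_value = qt$p_value)
        }
      }
      if (length(sf$failed)) {
        report$warnings <- c(report$warnings,
                             sprintf("dimension %s: stratum level(s) failed: %s",
                                     d, paste(names(sf$failed),
                                              collapse = ", ")))
      }
    }
    stratified <- do.call(rbind, strat_rows)
    qtests <- do.call(rbind, q_rows)
    note("stratify", t0)
    utils::write.csv(stratified, file.path(config$outdir, "stratified.csv"),
                     row.names = FALSE)
    utils::write.csv(qtests, file.path(config$outdir, "qtests.csv"),
                     row.names = FALSE)

    t0 <- tic()
    desc <- descriptives(inputs$events)
    utils::write.csv(desc, file.path(config$outdir, "descriptives.csv"),
                     row.names = FALSE)
    note("descriptives", t0)
  }, warning = function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  report$config <- list(
    source = if (is.null(config$synthetic)) "paths" else "synthetic",
    seed = config$seed,
    model = list(exposure = spec$exposure, form = spec$form,
                 df = spec$df %||% NA, covariates = config$model$covariates,
                 referent = spec$referent),
    select_aic = config$select_aic, mean_mm = config$mean_mm,
    stratify_dimensions = config$stratify_dimensions
  )
  report$n_events <- nrow(inputs$events)
  report$n_strata <- length(unique(strata$stratum_id))
  report$n_strata_fitted <- fit$n_strata
  report$n_strata_dropped <- report$n_strata - fit$n_strata
  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(inputs = inputs, strata = strata, linked = linked,
                 selection = sel, fit = fit, spec = spec,
                 percentiles = pct, or_table = or_tab, curve = curve,
                 tracts_ice = tracts_ice, tercile_summary = rates,
                 stratified = stratified, qtests = qtests,
                 descriptives = desc, report = report))
}

#' Descriptive frequency table of event attributes
#'
#' Counts and percentages per level of each supplied attribute
#' (missing values tallied as `"Unknown"`); percentages are
#' `100 * count / n_events`, rounded to one decimal.  A `season`
#' attribute is derived from the event date (meteorological seasons:
#' Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov fall) when
#' absent.
#'
#' @param events Event data frame; attribute columns are any of
#'   `gender`, `age_band`, `race`, `cause`, `region`, `season` that are
#'   present.
#' @param attributes Attribute columns to tabulate.
#' @return Long data frame: `attribute`, `level`, `count`, `pct`.
#' @export
descriptives <- function(events,
                         attributes = c("gender", "age_band", "race",
                                        "cause", "region", "season")) {
  n <- nrow(events)
  if (!"season" %in% names(events) && "date" %in% names(events)) {
    events$season <- meteorological_season(events$date)
  }
  attributes <- intersect(attributes, names(events))
  out <- lapply(attributes, function(a) {
    v <- as.character(events[[a]])
    v[is.na(v) | v == ""] <- "Unknown"
    tab <- table(v)
    data.frame(attribute = a, level = names(tab),
               count = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Meteorological season of a date
#'
#' @param date Vector coercible to `Date`.
#' @return Character vector in
#'   `{"Winter", "Spring", "Summer", "Fall"}` (Dec-Feb winter).
#' @export
meteorological_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer", "Summer",
    "Summer", "Fall", "Fall", "Fall", "Winter")[m]
}
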