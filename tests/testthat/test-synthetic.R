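test_that("degenerate generator collapses to the cell mean", {
  cfg <- synthetic_config(n_cells = 3L, seasonal_amplitude = 0, noise_sd = 0,
                          date_start = "2013-01-01", date_end = "2013-06-30",
                          seed = 1L)
  w <- generate_weather(cfg)
  cells <- weather_cells(w)
  expect_equal(w$tmax_c, cells$mean_tmax_c[match(w$cell_id, cells$cell_id)])
  expect_equal(w$tmean_c, w$tmax_c - 8)
})

test_that("same seed reproduces every table exactly", {
  cfg <- synthetic_config(n_cells = 4L, date_start = "2013-01-01",
                          date_end = "2013-12-31", seed = 11L)
  w1 <- generate_weather(cfg); w2 <- generate_weather(cfg)
  expect_identical(w1, w2)
  e1 <- generate_events(cfg, w1); e2 <- generate_events(cfg, w2)
  expect_identical(e1, e2)
  expect_identical(generate_tracts(cfg), generate_tracts(cfg))
})

test_that("weather noise SD is recovered after deseasonalizing", {
  cfg <- synthetic_config(n_cells = 1L, noise_sd = 2,
                          date_start = "2005-01-01",
                          date_end = "2014-12-31", seed = 5L)
  w <- generate_weather(cfg)
  cells <- weather_cells(w)
  doy <- as.POSIXlt(w$date)$yday + 1
  seasonal <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  resid <- w$tmax_c - cells$mean_tmax_c[1] - seasonal
  expect_gt(sd(resid), 1.8)
  expect_lt(sd(resid), 2.2)
})

test_that("a short date range is refused", {
  cfg <- synthetic_config(date_start = "2013-01-01",
                          date_end = "2013-02-15", seed = 1L)
  expect_error(generate_weather(cfg), "60 days")
})

test_that("null effects give the configured marginal event rate", {
  cfg <- synthetic_config(n_cells = 10L, beta_temp = 0, gamma_holiday = 0,
                          cell_sd = 0, baseline_rate = 0.08,
                          date_start = "2013-01-01",
                          date_end = "2014-12-31", seed = 21L)
  w <- generate_weather(cfg)
  ev <- generate_events(cfg, w)
  n <- nrow(w)
  rate <- nrow(ev) / n
  se <- sqrt(0.08 * 0.92 / n)
  expect_lt(abs(rate - 0.08), 3 * se)
})

test_that("vanishing baseline rate gives no events", {
  cfg <- synthetic_config(n_cells = 3L, baseline_rate = 1e-12,
                          date_start = "2013-01-01",
                          date_end = "2013-12-31", seed = 3L)
  w <- generate_weather(cfg)
  expect_identical(nrow(generate_events(cfg, w)), 0L)
})

test_that("a positive temperature effect selects warmer event days", {
  cfg <- synthetic_config(n_cells = 10L, beta_temp = 0.1,
                          date_start = "2013-01-01",
                          date_end = "2014-12-31", seed = 31L)
  w <- generate_weather(cfg)
  ev <- generate_events(cfg, w)
  idx <- match(paste(ev$cell_id, ev$date), paste(w$cell_id, w$date))
  expect_gt(mean(w$tmax_c[idx]), mean(w$tmax_c))
})

test_that("tract tables respect count constraints and span all terciles", {
  cfg <- synthetic_config(n_tracts = 300L, seed = 41L)
  tr <- generate_tracts(cfg)
  expect_identical(nrow(tr), 300L)
  expect_true(all(tr$pop_total > 0))
  for (d in ice_dimensions()) {
    a <- tr[[paste0(d, "_privileged")]]
    p <- tr[[paste0(d, "_deprived")]]
    expect_true(all(a >= 0 & p >= 0))
    expect_true(all(a + p <= tr$pop_total))
  }
  ice <- compute_ice(tr)
  for (d in ice_dimensions()) {
    v <- ice[[paste0("ice_", d)]]
    terc <- assign_tercile(v, tercile_cutpoints(v))
    expect_setequal(unique(terc), 1:3)
  }
})

test_that("ground truth is recoverable and seed-stable", {
  cfg <- synthetic_config(n_cells = 3L, seed = 51L,
                          date_start = "2013-01-01",
                          date_end = "2013-12-31")
  w <- generate_weather(cfg)
  tr1 <- ground_truth(generate_events(cfg, w))
  tr2 <- ground_truth(generate_events(cfg, w))
  expect_identical(tr1, tr2)
  expect_equal(tr1$beta_temp, cfg$beta_temp)
  expect_length(tr1$baseline_log_odds, cfg$n_cells)
})

test_that("written synthetic study round-trips through CSV", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_cells = 3L, n_tracts = 10L, seed = 61L,
                          date_start = "2013-01-01",
                          date_end = "2013-12-31")
  res <- write_synthetic_data(cfg, dir)
  expect_setequal(list.files(dir),
                  c("events.csv", "weather.csv", "cells.csv", "tracts.csv",
                    "truth.json"))
  ev <- read.csv(file.path(dir, "events.csv"))
  expect_identical(nrow(ev), nrow(res$events))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta_temp, cfg$beta_temp)
})
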