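test_that("nearest cell honors exact centres and the id tie-break", {
  cells <- data.frame(cell_id = c(3L, 1L, 2L), lon = c(-100, -101, -99),
                      lat = c(40, 40, 40))
  expect_identical(nearest_cell(-101, 40, cells), 1L)
  # point equidistant from cells 1 and 2 -> smaller id wins
  expect_identical(nearest_cell(-100, 40, cells), 3L)  # exact centre first
  cells2 <- data.frame(cell_id = c(2L, 1L), lon = c(-99, -101), lat = c(40, 40))
  expect_identical(nearest_cell(-100, 40, cells2), 1L)
  expect_error(nearest_cell(-100, 40, cells[0, ]), "empty")
})

test_that("nearest cell matches an exhaustive distance scan", {
  set.seed(13)
  cells <- data.frame(cell_id = sample.int(100L, 40L),
                      lon = runif(40, -120, -75), lat = runif(40, 25, 49))
  lon <- runif(25, -120, -75); lat <- runif(25, 25, 49)
  got <- nearest_cell(lon, lat, cells)
  want <- vapply(seq_along(lon), function(i) {
    d <- haversine_m(lon[i], lat[i], cells$lon, cells$lat)
    cand <- cells$cell_id[d <= min(d) + 1e-9]
    min(cand)
  }, integer(1))
  expect_identical(got, want)
})

test_that("precipitation categories follow the dry/below-mean/at-or-above rule", {
  expect_identical(precip_category(0), 0L)
  expect_identical(precip_category(1.0), 1L)
  expect_identical(precip_category(5.0), 2L)
  expect_identical(precip_category(2.68), 2L)  # boundary goes wetter
  expect_error(precip_category(-1), "negative")
  # monotone non-decreasing in rainfall for a fixed mean
  x <- sort(c(0, runif(50, 0, 8)))
  expect_true(all(diff(precip_category(x, 2.68)) >= 0))
})

test_that("US federal holiday table behaves, with observed shifting", {
  hol <- us_holidays(2013:2024)
  expect_true(is_holiday(as.Date("2023-07-04"), hol))
  expect_false(is_holiday(as.Date("2023-07-06"), hol))
  expect_true(is_holiday(as.Date("2023-11-23"), hol))  # 4th Thursday
  # July 4 2021 fell on a Sunday: observed Monday July 5
  expect_true(is_holiday(as.Date("2021-07-05"), hol))
  # Juneteenth 2021 (Saturday): observed Friday June 18; absent before 2021
  expect_true(is_holiday(as.Date("2021-06-18"), hol))
  expect_false(is_holiday(as.Date("2020-06-19"), hol))
  expect_error(is_holiday(as.Date("2030-01-01"), hol), "coverage")
})

test_that("an empty holiday table with declared coverage is always false", {
  hol <- holiday_table(as.Date(character(0)), coverage_years = 2013:2024)
  expect_false(any(is_holiday(as.Date("2023-07-04") + 0:30, hol)))
})

test_that("linkage copies exposures exactly and flags stratum days", {
  s <- small_study(seed = 81L)
  li <- s$linked
  expect_identical(nrow(li), nrow(s$strata))
  key_w <- paste(s$weather$cell_id, s$weather$date)
  idx <- match(paste(li$cell_id, li$date), key_w)
  expect_identical(li$dtmax_c, s$weather$tmax_c[idx])
  expect_identical(li$dtmean_c, s$weather$tmean_c[idx])
  expect_identical(li$precip_cat,
                   precip_category(s$weather$precip_mm[idx], 2.68))
  # within a stratum all days share the cell
  expect_true(all(tapply(li$cell_id, li$stratum_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("a stratum with any missing weather day is dropped whole", {
  s <- small_study(seed = 91L)
  victim <- s$strata$stratum_id[1L]
  vday <- s$strata$date[s$strata$stratum_id == victim][2L]
  vcell <- s$strata$cell_id[1L]
  w <- s$weather[!(s$weather$cell_id == vcell & s$weather$date == vday), ]
  # every stratum touching the removed cell-day must go, whole
  doomed <- unique(s$strata$stratum_id[s$strata$cell_id == vcell &
                                         s$strata$date == vday])
  expect_warning(li <- link_exposures(s$strata, w),
                 sprintf("dropping %d", length(doomed)))
  expect_false(any(doomed %in% li$stratum_id))
  n_removed <- sum(s$strata$stratum_id %in% doomed)
  expect_identical(nrow(li), nrow(s$strata) - n_removed)
})
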