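test_that("haversine matches closed forms and an independent implementation", {
  expect_equal(haversine_km(12, -70, 12, -70), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 6371 * pi / 180, tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 0, 180), 6371 * pi, tolerance = 1e-9)
  expect_equal(haversine_km(10, -60, 20, -80), haversine_km(20, -80, 10, -60))
  expect_error(haversine_km(95, 0, 0, 0), "out of range")

  skip_if_not_installed("geosphere")
  set.seed(11)
  p1 <- cbind(runif(50, -170, 170), runif(50, -80, 80))
  p2 <- cbind(runif(50, -170, 170), runif(50, -80, 80))
  ref <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  expect_equal(haversine_km(p1[, 2], p1[, 1], p2[, 2], p2[, 1]), ref,
               tolerance = 1e-9)
})

test_that("minimum track distance agrees with a per-point scan, ties earliest", {
  reef <- c(lat = 17.5, lon = -64.0)
  tr <- make_track(lat = 17 + cumsum(runif(20, 0, 0.3)),
                   lon = -66 + cumsum(runif(20, 0, 0.4)))
  res <- min_track_distance(tr, reef["lat"], reef["lon"])
  brute <- vapply(seq_len(nrow(tr)), function(i)
    haversine_km(reef["lat"], reef["lon"], tr$lat[i], tr$lon[i]), numeric(1))
  expect_equal(res$distance_km, min(brute))
  expect_equal(res$closest_point, which.min(brute))

  over <- make_track(lat = c(17.5, 18), lon = c(-64, -63.5))
  expect_equal(min_track_distance(over, 17.5, -64)$distance_km, 0)

  single <- make_track(lat = 18, lon = -64)
  expect_equal(min_track_distance(single, 17.5, -64)$distance_km,
               haversine_km(17.5, -64, 18, -64))

  # equidistant points: earliest index wins
  sym <- make_track(lat = c(17, 18), lon = c(-64, -64))
  expect_equal(min_track_distance(sym, 17.5, -64)$closest_point, 1L)
})

test_that("retention follows the tiered distance/category rules", {
  # any strength within 35 km
  expect_true(retention_decision(30, "TS")$retained)
  expect_equal(retention_decision(30, "TS")$band, "<=35")
  # category 3-5 only in the middle band
  expect_false(retention_decision(50, "2")$retained)
  expect_true(retention_decision(50, "3")$retained)
  # category 4-5 only in the outer band
  expect_true(retention_decision(80, "4")$retained)
  expect_equal(retention_decision(80, "4")$band, "65-100")
  expect_false(retention_decision(80, "3")$retained)
  # nothing beyond 100 km
  expect_false(retention_decision(120, "5")$retained)
  expect_error(retention_decision(10, "6"), "category")
})

test_that("strict band mode leaves the 60-65 km sliver unretained", {
  expect_true(retention_decision(62, "3", band_mode = "contiguous")$retained)
  expect_false(retention_decision(62, "3", band_mode = "strict")$retained)
  expect_false(retention_decision(62, "5", band_mode = "strict")$retained)
  expect_true(retention_decision(58, "3", band_mode = "strict")$retained)
  expect_equal(retention_decision(58, "3", band_mode = "strict")$band, "35-60")
  expect_true(retention_decision(70, "4", band_mode = "strict")$retained)
})

test_that("retention is monotone in category at fixed distance", {
  lv <- c("below_TS", "TS", "1", "2", "3", "4", "5")
  for (d in c(10, 35, 36, 50, 65, 66, 80, 100, 101)) {
    ret <- retention_decision(rep(d, 7), lv)$retained
    expect_true(all(diff(as.integer(ret)) >= 0),
                label = paste("monotone at", d, "km"))
  }
})

test_that("catalog equals the brute-force oracle and orders deterministically", {
  w <- small_world()
  got <- build_intersection_catalog(w$tracks, w$sites)
  expect_gt(nrow(got), 0)
  expect_equal(anyDuplicated(got[c("site_id", "storm_id")]), 0L)
  expect_true(all(got$min_distance_km <= 100))
  expect_identical(got, dplyr::arrange(got, site_id, year, storm_id))

  skip_if_not_installed("geosphere")
  want <- oracle_catalog(w$tracks, w$sites)
  expect_equal(nrow(got), nrow(want))
  got_o <- got[order(got$site_id, got$storm_id), ]
  expect_equal(got_o$site_id, want$site_id)
  expect_equal(got_o$storm_id, want$storm_id)
  expect_equal(got_o$min_distance_km, want$min_distance_km, tolerance = 1e-9)
  expect_equal(got_o$band, want$band)
})

test_that("degenerate catalog inputs behave", {
  sites <- make_sites(lat = c(17.0, 17.5, 18.0), lon = c(-64, -64, -64))
  expect_equal(nrow(build_intersection_catalog(empty_track_tbl_for_test(), sites)), 0)

  over <- make_track(lat = c(16.5, 17.0, 17.5, 18.0), lon = rep(-64, 4),
                     wind = rep(80, 4))
  cat <- build_intersection_catalog(over, sites)
  expect_equal(nrow(cat), 3) # one storm passing exactly over 3 reefs
  expect_equal(cat$min_distance_km, rep(0, 3))

  dup <- make_sites(lat = c(17, 17), lon = c(-64, -64))
  expect_error(build_intersection_catalog(over, dup), "unique")
})

test_that("return time is the mean inter-event gap", {
  expect_equal(return_time(c(1980, 1990, 2000)), 10)
  expect_equal(return_time(c(1980, 1981, 1999)), 9.5)
  expect_equal(return_time(c(1999, 1981, 1980)), 9.5) # order-free
  expect_true(is.na(return_time(1980)))
})

test_that("dispersion statistic and classes follow variance/mean - 1", {
  expect_equal(dispersion_statistic(c(1, 1, 1)),
               tibble::tibble(psi = -1, class = "regular"))
  expect_equal(dispersion_statistic(c(0, 1, 2)),
               tibble::tibble(psi = 0, class = "stochastic"))
  expect_equal(dispersion_statistic(c(4, 0, 0, 0)),
               tibble::tibble(psi = 3, class = "clustered"))
  expect_true(is.na(dispersion_statistic(c(0, 0, 0))$psi))
  # practical tolerance absorbs small departures
  expect_equal(dispersion_statistic(c(0, 1, 2, 1, 1), tol = 0.5)$class,
               "stochastic")
})

test_that("weighted intensity is an inverse-distance mean within input range", {
  expect_equal(weighted_mean_intensity(57, 95), 95)
  expect_equal(weighted_mean_intensity(c(40, 40), c(80, 120)), 100)
  expect_equal(weighted_mean_intensity(c(1, 99), c(100, 50)), 99.5)
  expect_true(is.na(weighted_mean_intensity(numeric(), numeric())))
  set.seed(5)
  for (i in 1:20) {
    d <- runif(6, 0, 100); p <- runif(6, 34, 150)
    wm <- weighted_mean_intensity(d, p)
    expect_gte(wm, min(p)); expect_lte(wm, max(p))
  }
})

test_that("per-reef regime metrics summarise the catalog", {
  cat <- dplyr::bind_rows(
    make_catalog_row("sA", "AL011980", 1980, dist = 10),
    make_catalog_row("sA", "AL011990", 1990, dist = 20),
    make_catalog_row("sA", "AL012000", 2000, dist = 30)
  )
  peaks <- tibble::tibble(storm_id = c("AL011980", "AL011990", "AL012000"),
                          peak_wind = c(100, 80, 120))
  sites <- make_sites(lat = c(17, 18), lon = c(-64, -65), ids = c("sA", "sB"))
  reg <- disturbance_regime(cat, peaks, sites = sites, window = c(1975, 2004))
  expect_equal(reg$n_storms, c(3L, 0L))
  expect_equal(reg$return_time_yr[1], 10)
  expect_true(is.na(reg$return_time_yr[2]))
  counts <- tabulate(factor(c(1980, 1990, 2000), levels = 1975:2004), nbins = 30)
  expect_equal(reg$psi[1], var(counts) / mean(counts) - 1)
  w <- 1 / c(10, 20, 30)
  expect_equal(reg$weighted_mean_intensity_kt[1],
               sum(w * c(100, 80, 120)) / sum(w))
})
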