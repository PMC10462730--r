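test_that("pre/post matching is exact by default and tolerant on request", {
  cat <- make_catalog_row("s1", "AL012000", 2000)
  ser <- make_series("s1", c(1999, 2001), c(20, 15))
  ev <- match_pre_post(ser, cat)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pre_cover, 20)
  expect_equal(ev$post_cover, 15)
  expect_true(ev$matched_exact)

  # missing post year -> no event under default settings
  gap <- make_series("s1", 1999, 20)
  expect_equal(nrow(match_pre_post(gap, cat)), 0)

  # tolerance window picks the nearest surveys and flags the event
  wide <- make_series("s1", c(1998, 2002), c(20, 15))
  expect_equal(nrow(match_pre_post(wide, cat)), 0)
  ev2 <- match_pre_post(wide, cat, tolerance = 2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$pre_year, 1998L)
  expect_equal(ev2$post_year, 2002L)
  expect_false(ev2$matched_exact)
  # the impact year itself is never used as the pre survey
  impact_yr <- make_series("s1", c(2000, 2001), c(18, 15))
  expect_equal(nrow(match_pre_post(impact_yr, cat, tolerance = 2)), 0)
})

test_that("resistance formulas and sign agreement", {
  expect_equal(resistance(20, 15),
               tibble::tibble(resistance_abs = -5, resistance_rel = -25))
  expect_equal(resistance(10, 10),
               tibble::tibble(resistance_abs = 0, resistance_rel = 0))
  zero <- resistance(0, 5)
  expect_equal(zero$resistance_abs, 5)
  expect_true(is.na(zero$resistance_rel))

  set.seed(2)
  pre <- runif(100, 1, 60); post <- pmax(pre + rnorm(100, 0, 10), 0)
  r <- resistance(pre, pmin(post, 100))
  expect_true(all(sign(r$resistance_abs) == sign(r$resistance_rel) |
                    r$resistance_abs == 0))
})

test_that("relative recovery is anchored at zero one year pre-storm", {
  ser <- make_series("s1", c(1999, 2001, 2003), c(20, 15, 17))
  rr <- relative_recovery(ser, 2000)
  expect_equal(rr$offset, c(-1, 1, 3))
  expect_equal(rr$delta, c(0, -5, -3))

  flat <- make_series("s1", 1997:2003, rep(12, 7))
  expect_true(all(relative_recovery(flat, 2000)$delta == 0))

  only_init <- make_series("s1", 1999, 20)
  expect_equal(relative_recovery(only_init, 2000)$delta, 0)
  expect_error(relative_recovery(make_series("s1", 1998, 20), 2000),
               "initial conditions")
})

test_that("CR depends only on the post-storm endpoints", {
  ser <- make_series("s1", c(2001, 2003, 2005), c(10, 55, 8))
  out <- cr_rate(ser, 2000)
  expect_equal(out$cr, (8 - 10) / 4)
  expect_equal(out$d, 4)

  # intermediate values are irrelevant
  ser2 <- make_series("s1", c(2001, 2003, 2005), c(10, 0, 8))
  expect_equal(cr_rate(ser2, 2000)$cr, out$cr)

  expect_equal(cr_rate(make_series("s1", c(2001, 2004), c(10, 13)), 2000)$cr, 1)
  expect_equal(cr_rate(make_series("s1", c(2001, 2006), c(9, 9)), 2000)$cr, 0)
  expect_true(is.na(cr_rate(make_series("s1", c(2002, 2005), c(10, 8)), 2000)$cr))
  expect_true(is.na(cr_rate(make_series("s1", 2001, 10), 2000)$cr))
})

test_that("same site/year events keep the stronger then later storm", {
  ev <- dplyr::bind_rows(
    dplyr::mutate(make_catalog_row("s1", "AL012000", 2000, month = 8),
                  impact_year = 2000L),
    dplyr::mutate(make_catalog_row("s1", "AL022000", 2000, month = 10),
                  impact_year = 2000L)
  )
  peaks <- tibble::tibble(storm_id = c("AL012000", "AL022000"),
                          peak_wind = c(100, 120))
  expect_equal(select_event_for_cr(ev, peaks)$storm_id, "AL022000")

  tie <- tibble::tibble(storm_id = c("AL012000", "AL022000"),
                        peak_wind = c(100, 100))
  expect_equal(select_event_for_cr(ev, tie)$storm_id, "AL022000") # later date

  one <- ev[1, ]
  expect_equal(select_event_for_cr(one, peaks)$storm_id, "AL012000")
})

test_that("control selection honours the never-hit and >10-year rules", {
  ser <- make_series("s1", seq(1985, 2005, by = 1), seq(30, 20, length.out = 21))
  no_storms <- make_catalog_row("zz", "AL011990", 1990)[0, ]
  ctrl <- select_controls(ser, no_storms)
  expect_equal(nrow(ctrl), 1)
  expect_true(ctrl$never_hit)
  expect_equal(ctrl$window_start, 1985L)
  expect_equal(ctrl$window_end, 2005L)
  expect_equal(ctrl$cr, (20 - 30) / 20)

  hit <- make_catalog_row("s1", "AL011990", 1990)
  ctrl2 <- select_controls(ser, hit)
  # pre-storm years qualify; 1991-2000 are excluded; >10 yr after qualifies
  expect_equal(sort(unique(ctrl2$window_start)), c(1985L, 2001L))
  expect_equal(ctrl2$window_end[ctrl2$window_start == 1985], 1989L)
  expect_equal(ctrl2$window_start[ctrl2$window_start > 1990], 2001L)

  two <- dplyr::bind_rows(hit, make_catalog_row("s1", "AL011998", 1998))
  ctrl3 <- select_controls(ser, two)
  # no window opens between 1990 and 1998 + 10
  expect_true(all(ctrl3$window_start <= 1989 | ctrl3$window_start >= 2009))
})

test_that("control windows never overlap a retained intersection", {
  w <- small_world()
  tot <- annual_series(w$surveys)
  ctrl <- select_controls(tot, w$catalog)
  overlaps <- dplyr::inner_join(ctrl, w$catalog, by = "site_id",
                                relationship = "many-to-many") |>
    dplyr::filter(year >= window_start, year <= window_end)
  expect_equal(nrow(overlaps), 0)
})

test_that("decadal summaries report bootstrap limits and degeneracies", {
  df <- tibble::tibble(year = c(rep(1985, 5), 1995),
                       cr = c(rep(-0.5, 5), 0.2))
  out <- decadal_summary(df, "cr", seed = 9)
  expect_equal(out$decade, c(1980, 1990))
  # all-equal cell: interval collapses to the constant
  expect_equal(out$ci_lo[1], -0.5)
  expect_equal(out$ci_hi[1], -0.5)
  expect_false(out$degenerate[1])
  # single-record cell: mean reported, limits NA, flagged
  expect_equal(out$mean[2], 0.2)
  expect_true(is.na(out$ci_lo[2]))
  expect_true(out$degenerate[2])
  expect_equal(out$n, c(5L, 1L))
})
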