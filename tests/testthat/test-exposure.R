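test_that("active window honours the 5-day cap and 24-h weaning rule", {
  ep <- function(...) {
    m <- matrix(c(..., numeric(0)), ncol = 2, byrow = TRUE)
    data.frame(start_h = m[, 1], stop_h = m[, 2])
  }
  expect_equal(active_window(ep(0, 130)), c(0, 120))
  expect_equal(active_window(ep(0, 60)), c(0, 60))
  expect_equal(active_window(ep(0, 40, 50, 90)), c(0, 90)) # 10-h gap: continues
  expect_equal(active_window(ep(0, 40, 70, 90)), c(0, 40)) # 30-h gap: weaned
  expect_equal(active_window(ep(0, 40, 50, 90, 130, 140)), c(0, 90))
  expect_error(active_window(ep()), class = "mapdeficit_empty_window")
})

test_that("deficit_at is the signed percentage shortfall", {
  expect_equal(deficit_at(100, 80), 20)
  expect_equal(deficit_at(94, 83), 100 * 11 / 94) # 11.70 to 2 d.p.
  expect_equal(deficit_at(80, 90), -12.5)
  expect_error(deficit_at(0, 80), class = "mapdeficit_contract_error")
})

test_that("twa_map_deficit integrates the positive part with exact crossings", {
  # constant 20% deficit, any duration
  expect_equal(twa_map_deficit(c(0, 4, 16), rep(80, 3), 100), 20)
  # deficit 10 -> -10 crosses zero at t = 2: area 10 %.h over 4 h
  expect_equal(twa_map_deficit(c(0, 4), c(90, 110), 100), 2.5)
  # mirrored upward crossing
  expect_equal(twa_map_deficit(c(0, 4), c(110, 90), 100), 2.5)
  # never below the pre-illness MAP
  expect_equal(twa_map_deficit(c(0, 4, 8), c(100, 105, 120), 100), 0)
  # single observation: positive part at that point
  expect_equal(twa_map_deficit(0, 80, 100), 20)
  expect_equal(twa_map_deficit(0, 110, 100), 0)
  expect_error(twa_map_deficit(numeric(0), numeric(0), 100),
               class = "mapdeficit_empty_series")
})

test_that("twa_map_deficit matches fine-grid Riemann integration", {
  withr::with_seed(101, {
    for (i in 1:200) {
      s <- random_map_series()
      expect_equal(twa_map_deficit(s$t, s$map, s$pre),
                   riemann_twa_deficit(s$t, s$map, s$pre),
                   tolerance = 1e-6)
    }
  })
})

test_that("twa_map_deficit is invariant to collinear insertions", {
  withr::with_seed(102, {
    for (i in 1:50) {
      s <- random_map_series()
      k <- sample(length(s$t) - 1, 1)
      tm <- (s$t[k] + s$t[k + 1]) / 2
      mm <- (s$map[k] + s$map[k + 1]) / 2 # on the segment's line
      t2 <- append(s$t, tm, after = k)
      m2 <- append(s$map, mm, after = k)
      expect_equal(twa_map_deficit(t2, m2, s$pre),
                   twa_map_deficit(s$t, s$map, s$pre), tolerance = 1e-12)
    }
  })
})

test_that("with no excursions above pre-illness MAP the iAUC is the plain trapezoid", {
  withr::with_seed(103, {
    for (i in 1:30) {
      s <- random_map_series()
      map <- pmin(s$map, s$pre - 0.5) # keep the deficit strictly positive
      d <- deficit_at(s$pre, map)
      n <- length(d)
      trapz <- sum((d[-n] + d[-1]) / 2 * diff(s$t)) / (max(s$t) - min(s$t))
      expect_equal(twa_map_deficit(s$t, map, s$pre), trapz, tolerance = 1e-12)
    }
  })
})

test_that("threshold-time fractions classify intervals by their left endpoint", {
  pre <- 100
  # deficits [25, 10, 25]: intervals classified 25 and 10 -> one of two
  expect_equal(pct_time_deficit_above(c(0, 4, 8), c(75, 90, 75), pre), 50)
  expect_equal(pct_time_deficit_above(c(0, 4, 8), rep(75, 3), pre), 100)
  # deficits [25, 25, 10, 10, 10] equally spaced -> 2 of 4 intervals
  expect_equal(pct_time_deficit_above(seq(0, 16, 4),
                                      c(75, 75, 90, 90, 90), pre), 50)
  expect_equal(pct_time_map_below(c(0, 4, 8), c(60, 70, 70)), 50)
  expect_equal(pct_time_map_below(c(0, 4, 8), c(66, 70, 70)), 0)
  # left-endpoint rule: both intervals of [64, 64, 66] classify below 65
  expect_equal(pct_time_map_below(c(0, 4, 8), c(64, 64, 66)), 100)
  expect_true(is.na(pct_time_map_below(0, 64)))
})

test_that("intervals touching a missing observation drop from both sides", {
  t <- c(0, 4, 8, 12, 16)
  map <- c(60, NA, 60, 70, 70)
  # usable intervals: [8,12) and [12,16): classified 60 (below) and 70
  expect_equal(pct_time_map_below(t, map), 50)
  # deficits at usable left endpoints: 40 and 30 -> one of two above 35
  expect_equal(pct_time_deficit_above(t, map, 100, threshold = 35), 50)
})

test_that("threshold fractions and their complements sum to 100", {
  withr::with_seed(104, {
    for (i in 1:30) {
      s <- random_map_series()
      below <- pct_time_map_below(s$t, s$map, cutoff = 70)
      above <- 100 - mapdeficit:::pct_time_classified(s$t, s$map,
                                                      function(x) x >= 70)
      expect_equal(below, above, tolerance = 1e-9)
      expect_gte(below, 0); expect_lte(below, 100)
    }
  })
})

test_that("achieved MAP is the trapezoidal time-weighted mean", {
  expect_equal(achieved_map(c(0, 4, 8), rep(77, 3)), 77)
  expect_equal(achieved_map(c(0, 4), c(70, 90)), 80)
  expect_equal(achieved_map(c(0, 4, 8), c(80, 80, 100)), 85) # (320+360)/8
  expect_equal(achieved_map(0, 83), 83)
  withr::with_seed(105, {
    for (i in 1:20) {
      s <- random_map_series()
      a <- achieved_map(s$t, s$map)
      expect_gte(a, min(s$map)); expect_lte(a, max(s$map))
    }
  })
})

test_that("daily extremes use T0-anchored 24-h windows and skip empty days", {
  de <- daily_extremes(c(0, 8, 20), c(70, 90, 80))
  expect_equal(de$day, 1L)
  expect_equal(de$highest_map, 90)
  expect_equal(de$lowest_map, 70)
  # nothing observed in day 2 (hours 24-48)
  de2 <- daily_extremes(c(0, 20, 50, 60), c(70, 75, 80, 85))
  expect_equal(de2$day, c(1L, 3L))
  expect_true(all(de2$lowest_map <= de2$highest_map))
})

test_that("deficit profile crosses deficit bins with dose escalation", {
  pre <- 100
  p1 <- deficit_profile(c(0, 4, 8), rep(95, 3), rep(0.1, 3), pre)
  expect_equal(p1$pct_time[p1$deficit_bin == "<10" & !p1$escalation], 100)
  p2 <- deficit_profile(c(0, 4), c(75, 75), c(0.1, 0.2), pre)
  expect_equal(p2$pct_time[p2$deficit_bin == ">20" & p2$escalation], 100)
  # four equal intervals split across bins: occupancies conserve time
  p3 <- deficit_profile(seq(0, 16, 4), c(95, 85, 75, 95, 85),
                        c(0.1, 0.2, 0.1, 0.1, 0.2), pre)
  expect_equal(sum(p3$pct_time), 100, tolerance = 1e-9)
  # a missing dose at the shared endpoint excludes both adjacent intervals,
  # leaving nothing classified
  p4 <- deficit_profile(c(0, 4, 8), c(75, 75, 75), c(0.1, NA, 0.1), pre)
  expect_true(all(is.na(p4$pct_time)))
  # with one usable interval remaining, it carries all the occupancy
  p5 <- deficit_profile(c(0, 4, 8), c(75, 75, 75), c(0.1, 0.2, NA), pre)
  expect_equal(p5$pct_time[p5$deficit_bin == ">20" & p5$escalation], 100)
})

test_that("exposure_summary composes the per-patient metrics", {
  vit <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 3),
    t_hours = rep(c(0, 4, 8), 2),
    map_mmHg = c(80, 80, 100, 60, 70, 70),
    ne_dose_ug_kg_min = 0.1
  )
  co <- tibble::tibble(patient_id = c("A", "B"), pre_illness_map = c(100, 100))
  es <- exposure_summary(vit, co)
  expect_equal(es$achieved_map, c(85, 67.5))
  expect_equal(es$twa_map_deficit[1], riemann_twa_deficit(c(0, 4, 8), c(80, 80, 100), 100),
               tolerance = 1e-6)
  expect_equal(es$pct_time_map_lt65, c(0, 50))
  expect_equal(es$total_observed_hours, c(8, 8))
})
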