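random_day <- function(seed) withr::with_seed(seed, runif(24, 0, 200))

test_that("interdaily stability limits", {
  day <- random_day(1)
  expect_equal(interdaily_stability(make_profile(rep(day, 3))), 1)
  expect_equal(interdaily_stability(make_profile(rep(day, 7))), 1)

  # mirrored second day: every clock-hour mean equals the grand mean
  mirrored <- c(day, 2 * mean(day) - day)
  expect_equal(interdaily_stability(make_profile(mirrored)), 0)

  expect_error(interdaily_stability(make_profile(rep(5, 72))), "zero-variance")
})

test_that("IS is invariant to affine count rescaling", {
  x <- withr::with_seed(2, runif(96, 0, 100))
  a <- interdaily_stability(make_profile(x))
  b <- interdaily_stability(make_profile(3 * x + 40))
  expect_equal(a, b)
})

test_that("intradaily variability closed forms", {
  alt <- rep(c(10, 90), 36)  # hourly alternation: algebraic maximum
  expect_equal(intradaily_variability(make_profile(alt)), 4,
               tolerance = 1e-12)

  # pure 24-h cosine, many days: IV -> 2 (1 - cos(2 pi / 24))
  h <- 0:(24 * 30 - 1)
  cosine <- 100 + 50 * cos(2 * pi * h / 24)
  expect_equal(intradaily_variability(make_profile(cosine)),
               2 * (1 - cos(2 * pi / 24)), tolerance = 0.01)

  expect_error(intradaily_variability(make_profile(rep(1, 30))), "zero-variance")
  expect_error(intradaily_variability(make_profile(runif(10))), "25 hourly")
})

test_that("IV skips pairs that span a missing hour", {
  x <- withr::with_seed(3, runif(72, 0, 100))
  x_na <- x; x_na[30] <- NA
  got <- intradaily_variability(make_profile(x_na))
  vals <- x_na[!is.na(x_na)]
  adjacent <- diff(which(!is.na(x_na))) == 1
  expect_equal(got, iv_ref(vals, adjacent))
})

test_that("IS and IV are invariant to adding a constant; RA is not", {
  x <- withr::with_seed(4, runif(96, 0, 100))
  expect_equal(interdaily_stability(make_profile(x)),
               interdaily_stability(make_profile(x + 57)))
  expect_equal(intradaily_variability(make_profile(x)),
               intradaily_variability(make_profile(x + 57)))
  ml <- m10_l5(make_profile(x))
  ml_shift <- m10_l5(make_profile(x + 57))
  expect_false(isTRUE(all.equal(ml$ra, ml_shift$ra)))
})

test_that("M10/L5 on a block signal", {
  h <- 0:23
  day <- ifelse(h >= 8 & h < 18, 100, 0)
  ml <- m10_l5(make_profile(rep(day, 2)))
  expect_equal(ml$m10, 100)
  expect_equal(ml$midpoint_m10_h, 13)
  expect_equal(ml$l5, 0)
  expect_equal(ml$ra, 1)
})

test_that("window search equals exhaustive circular evaluation", {
  for (s in 1:25) {
    day <- random_day(s + 100)
    ml <- m10_l5(make_profile(day))
    ref10 <- m10_l5_ref(day, 10)
    ref5 <- m10_l5_ref(day, 5)
    expect_equal(ml$m10, ref10$max_mean, tolerance = 1e-12)
    expect_equal(ml$midpoint_m10_h, ref10$max_mid)
    expect_equal(ml$l5, ref5$min_mean, tolerance = 1e-12)
    expect_equal(ml$midpoint_l5_h, ref5$min_mid)
  }
})

test_that("midpoints are averaged circularly across days", {
  # peaks straddling midnight: naive averaging of 23 h and 1 h would give noon
  day1 <- ifelse(0:23 %in% c(18:23, 0:3), 100, 0)  # M10 window [18, 4) -> mid 23
  day2 <- ifelse(0:23 %in% c(20:23, 0:5), 100, 0)  # [20, 6) -> mid 1
  ml <- m10_l5(make_profile(c(day1, day2)))
  expect_equal(ml$midpoint_m10_h, 0, tolerance = 0.01)
})

test_that("relative amplitude arithmetic and errors", {
  expect_equal(relative_amplitude(3, 1), 0.5)
  expect_equal(relative_amplitude(5, 5), 0)
  expect_equal(relative_amplitude(10, 0), 1)
  expect_error(relative_amplitude(0, 0), "undefined")
})

test_that("dichotomy index counts strictly-below in-bed epochs", {
  h <- clock_hours(make_epochs(rep(0, 1440))$time)
  in_bed <- h < 8
  out_counts <- rep(c(20, 30), length.out = sum(!in_bed))  # median 25

  cnt <- numeric(1440)
  cnt[!in_bed] <- out_counts
  cnt[in_bed] <- 0
  expect_equal(dichotomy_index(make_epochs(cnt, in_bed = in_bed)), 100)

  cnt[in_bed] <- rep(c(30, 10), length.out = sum(in_bed))
  expect_equal(dichotomy_index(make_epochs(cnt, in_bed = in_bed)), 50)

  cnt[in_bed] <- 25  # ties do not count under strict '<'
  expect_equal(dichotomy_index(make_epochs(cnt, in_bed = in_bed)), 0)

  expect_error(dichotomy_index(make_epochs(cnt)), "in-bed")
  expect_error(
    dichotomy_index(make_epochs(cnt, in_bed = rep(TRUE, 1440))),
    "out-of-bed")
})

test_that("rest intervals can define the in-bed set", {
  ep <- make_epochs(c(rep(0, 480), rep(100, 960)))
  rest <- tibble::tibble(rest_start = ep$time[1], rest_end = ep$time[480] + 60)
  expect_equal(dichotomy_index(ep, rest = rest), 100)
})

test_that("full-day indicator wrapper is coherent", {
  act <- simulate_activity(control_template()$rhythm, seed = 42)
  ind <- circadian_indicators(act)
  expect_true(ind$is > 0.8)               # highly repetitive by construction
  expect_true(ind$iv < 1)                 # smooth rhythm
  expect_true(ind$l5 <= ind$m10)
  # RA is averaged per day, so it agrees with the ratio of the averaged
  # extremes only approximately
  expect_equal(ind$ra, (ind$m10 - ind$l5) / (ind$m10 + ind$l5),
               tolerance = 0.01)
  expect_true(ind$dichotomy_index >= 0 && ind$dichotomy_index <= 100)
  expect_true(abs(ind$midpoint_m10_h - 13.5) <= 0.5)
})
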