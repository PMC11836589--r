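test_that("sleep scoring limits and window behaviour", {
  quiet <- score_sleep_wake(make_epochs(rep(0, 300)))
  expect_true(all(quiet$asleep))

  busy <- score_sleep_wake(make_epochs(rep(500, 300)))
  expect_false(any(busy$asleep))

  # an isolated still minute inside vigorous activity scores wake:
  # with default weights the central epoch contributes 230/665 of the mean,
  # so the window average is 200 * (1 - 230/665) = 130.8 > threshold 40
  cnt <- rep(200, 61); cnt[31] <- 0
  mid <- score_sleep_wake(make_epochs(cnt))$asleep[31]
  expect_false(mid)

  expect_error(score_sleep_wake(make_epochs(rep(0, 10), epoch_s = 30)), "60-s")
  expect_error(score_sleep_wake(make_epochs(rep(0, 10)), weights = rep(1, 5)),
               "7 non-negative")
})

scored_with_pattern <- function(asleep) {
  ep <- make_epochs(ifelse(asleep, 0, 300))
  ep$asleep <- asleep
  ep
}

test_that("major rest detection finds the dominant sleep span per day", {
  h2 <- clock_hours(make_epochs(rep(0, 2880))$time)
  rest <- detect_major_rest(scored_with_pattern(h2 >= 23 | h2 < 7))
  # the full overnight span [23:00, 07:00) is recovered on the interior night
  expect_true(any(clock_hours(rest$rest_start) == 23 &
                    clock_hours(rest$rest_end) == 7))
  expect_true(all(table(rest$date) == 1))

  h <- clock_hours(make_epochs(rep(0, 1440))$time)

  # two disjoint runs: the longest (6 h) wins
  asleep2 <- (h >= 1 & h < 5) | (h >= 14 & h < 20)
  rest2 <- detect_major_rest(scored_with_pattern(asleep2))
  expect_equal(nrow(rest2), 1)
  expect_equal(clock_hours(rest2$rest_start), 14)

  # no run of at least 3 h: empty result
  asleep3 <- h >= 2 & h < 4
  expect_equal(nrow(detect_major_rest(scored_with_pattern(asleep3))), 0)
})

test_that("sleep parameters follow their definitions exactly", {
  # fully asleep 480-min rest
  sc <- scored_with_pattern(c(rep(FALSE, 60), rep(TRUE, 480), rep(FALSE, 60)))
  rest <- tibble::tibble(rest_start = sc$time[61], rest_end = sc$time[540] + 60)
  p <- sleep_parameters(sc, rest)
  expect_equal(p$sol_min, 0)
  expect_equal(p$tst_min, 480)
  expect_equal(p$waso_min, 0)
  expect_equal(p$awakenings, 0L)
  expect_equal(p$se_pct, 100)

  # asleep from minute 20, one 30-min wake bout
  asleep <- c(rep(FALSE, 20), rep(TRUE, 200), rep(FALSE, 30), rep(TRUE, 230))
  sc <- scored_with_pattern(asleep)
  rest <- tibble::tibble(rest_start = sc$time[1], rest_end = sc$time[480] + 60)
  p <- sleep_parameters(sc, rest)
  expect_equal(p$sol_min, 20)
  expect_equal(p$tst_min, 430)
  expect_equal(p$waso_min, 30)
  expect_equal(p$awakenings, 1L)
  expect_equal(p$se_pct, 430 / 480 * 100)

  # empty rest set: zero rows with a warning
  expect_warning(p0 <- sleep_parameters(sc, rest = rest[0, ]), "no rest")
  expect_equal(nrow(p0), 0)
})

test_that("SOL + TST + WASO always equals rest duration", {
  for (s in 1:20) {
    asleep <- withr::with_seed(s, runif(480) < 0.8)
    sc <- scored_with_pattern(asleep)
    rest <- tibble::tibble(rest_start = sc$time[1], rest_end = sc$time[480] + 60)
    p <- sleep_parameters(sc, rest)
    expect_equal(p$sol_min + p$tst_min + p$waso_min, p$rest_min)
  }
})

test_that("injected wake bouts move WASO, awakenings and SE the right way", {
  base <- c(rep(FALSE, 10), rep(TRUE, 470))
  results <- purrr::map_dfr(c(0, 3, 8), function(k) {
    asleep <- base
    if (k > 0) {
      starts <- seq(60, 400, length.out = k)
      for (s in starts) asleep[s:(s + 9)] <- FALSE
    }
    sc <- scored_with_pattern(asleep)
    rest <- tibble::tibble(rest_start = sc$time[1], rest_end = sc$time[480] + 60)
    sleep_parameters(sc, rest)
  })
  expect_true(all(diff(results$waso_min) > 0))
  expect_true(all(diff(results$awakenings) > 0))
  expect_true(all(diff(results$se_pct) < 0))
})

test_that("annotated bed intervals override detection", {
  h <- clock_hours(make_epochs(rep(0, 1440))$time)
  ep <- make_epochs(ifelse(h >= 23 | h < 7, 0, 300),
                    in_bed = h >= 22 | h < 8)
  sc <- score_sleep_wake(ep)
  p <- sleep_parameters(sc)   # uses in_bed annotation
  expect_equal(sum(p$rest_min), 600)  # [00,08) and [22,24) runs
})
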