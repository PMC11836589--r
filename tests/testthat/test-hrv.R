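test_that("RR cleaning masks bounds and jump artefacts", {
  cl <- clean_rr(rep(800, 50))
  expect_true(all(cl$valid))

  x <- rep(800, 50); x[25] <- 4000
  cl <- clean_rr(x)
  expect_false(cl$valid[25])
  expect_equal(sum(!cl$valid), 1)

  # a 12.5% step is inside the default 20% tolerance
  cl <- clean_rr(c(rep(800, 10), rep(700, 10)))
  expect_true(all(cl$valid))

  # a 25% step is masked relative to the last valid interval
  x <- c(rep(800, 10), 1000, rep(800, 10))
  expect_false(clean_rr(x)$valid[11])

  expect_error(clean_rr(c(100, 100, 100)), "fewer than 2 valid")
})

test_that("time-domain metrics match hand computation", {
  td <- hrv_time_domain(c(800, 850, 790, 900))
  expect_equal(td$mean_rr, 835)
  expect_equal(td$hr, 60000 / 835)
  expect_equal(td$rmssd, sqrt((50^2 + 60^2 + 110^2) / 3))
  expect_equal(td$pnn50, 200 / 3)   # |50| > 50 is FALSE under strict '>'
  expect_equal(td$pnn20, 100)

  const <- hrv_time_domain(rep(900, 10))
  expect_equal(const$sdrr, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$pnn50, 0)

  expect_equal(hrv_time_domain(rep(1000, 5))$hr, 60)
})

test_that("difference metrics use only adjacent valid pairs", {
  rr <- tibble::tibble(rr_ms = c(800, 4000, 850), valid = c(TRUE, FALSE, TRUE))
  expect_error(hrv_time_domain(rr), "no adjacent valid")

  # metrics are invariant to invalid padding at the ends
  inner <- zero_mean_diff_rr(100, seed = 5)
  padded <- clean_rr(c(5000, inner, 5000))
  expect_equal(hrv_time_domain(padded)[, 1:6],
               hrv_time_domain(inner)[, 1:6])
  expect_equal(hrv_poincare(padded), hrv_poincare(inner))
})

test_that("Poincare dispersion algebra", {
  x <- zero_mean_diff_rr(200, seed = 1)
  pc <- hrv_poincare(x)
  td <- hrv_time_domain(x)
  # SD1 = RMSSD / sqrt(2) when the successive differences have zero mean
  expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 1e-2)
  # SDRR^2 = (SD1^2 + SD2^2) / 2 identically
  expect_equal((pc$sd1^2 + pc$sd2^2) / 2, td$sdrr^2, tolerance = 1e-12)

  expect_error(hrv_poincare(rep(800, 10)), "SD2 = 0|undefined")

  for (s in 1:10) {
    x <- withr::with_seed(s, 800 + cumsum(rnorm(300, 0, 20)))
    pc <- hrv_poincare(x)
    ref <- poincare_ref(x)
    expect_equal(pc$sd1, ref$sd1, tolerance = 1e-12)
    expect_equal(pc$sd2, ref$sd2, tolerance = 1e-12)
    geo <- poincare_geometric_ref(x)
    expect_equal(pc$sd1, geo$sd1, tolerance = 1e-12)  # identical pairs
    expect_equal(pc$sd2, geo$sd2, tolerance = 0.05)   # edge-term convention
  }
})

test_that("pNN20 >= pNN50 on arbitrary input", {
  for (s in 1:20) {
    x <- withr::with_seed(s, 800 + rnorm(200, 0, runif(1, 5, 80)))
    td <- hrv_time_domain(pmax(x, 310))
    expect_gte(td$pnn20, td$pnn50)
  }
})

test_that("deceleration capacity by phase-rectified averaging", {
  expect_error(deceleration_capacity(seq(1000, 600, by = -10)), "no deceleration")

  # alternating at exactly the 5% filter boundary: deceleration and
  # acceleration segments cancel
  alt <- rep(c(800, 840), 30)
  expect_equal(deceleration_capacity(alt), 0)

  # single isolated anchor: hand-computed quarter sum
  x <- c(800, 800, 800, 830, 800, 800, 800)
  expect_equal(deceleration_capacity(x), (830 + 800 - 800 - 800) / 4)

  for (s in 1:10) {
    x <- withr::with_seed(s, 800 + cumsum(rnorm(200, 0, 8)))
    x <- pmax(pmin(x, 1990), 310)
    got <- deceleration_capacity(x)
    expect_equal(got, unname(dc_ref(x)), tolerance = 1e-12)
  }
})

test_that("hrv_indicators assembles the full metric set", {
  rr <- simulate_rr(rr_sim_params(mean_rr_ms = 850, short_term_sd_ms = 25,
                                  long_term_sd_ms = 40, duration_min = 10),
                    seed = 9)
  ind <- hrv_indicators(rr)
  expect_equal(ind$sd_ratio, ind$sd1 / ind$sd2)
  expect_equal(ind$hr, 60000 / ind$mean_rr)
  expect_gte(ind$pnn20, ind$pnn50)
  expect_equal(ind$duration_min, 10, tolerance = 0.01)
  # DC undefined on monotone input surfaces as NA with a warning
  expect_warning(bad <- hrv_indicators(seq(1500, 500, length.out = 100)),
                 "DC undefined")
  expect_true(is.na(bad$dc))
})
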