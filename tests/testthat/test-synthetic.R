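test_that("noise-free limits of the activity generator are exact", {
  flat <- simulate_activity(
    rhythm_params(mesor = 80, amplitude = 0, fragmentation_p = 0,
                  day_noise_sd = 0, night_noise_sd = 0, n_days = 2),
    seed = 1)
  expect_true(all(flat$counts == 80))

  cosine <- simulate_activity(
    rhythm_params(mesor = 100, amplitude = 100, acrophase_h = 14,
                  fragmentation_p = 0, day_noise_sd = 0, night_noise_sd = 0,
                  n_days = 1),
    seed = 1)
  # rounding creates ties in the flat top; the acrophase epoch attains the max
  at_acrophase <- cosine$counts[clock_hours(cosine$time) == 14]
  expect_equal(at_acrophase, max(cosine$counts))
  expect_true(all(cosine$counts >= 0))
})

test_that("generators are deterministic under a fixed seed", {
  p <- rhythm_params(n_days = 2)
  expect_identical(simulate_activity(p, seed = 7), simulate_activity(p, seed = 7))
  expect_false(identical(simulate_activity(p, seed = 7)$counts,
                         simulate_activity(p, seed = 8)$counts))
  q <- rr_sim_params(duration_min = 2)
  expect_identical(simulate_rr(q, seed = 3), simulate_rr(q, seed = 3))
})

test_that("RR generator matches its stated construction", {
  const <- simulate_rr(rr_sim_params(mean_rr_ms = 1000, short_term_sd_ms = 0,
                                     long_term_sd_ms = 0, duration_min = 1),
                       seed = 1)
  expect_true(all(const$rr_ms == 1000))
  expect_equal(nrow(const), 60)

  # white short-term variability: RMSSD -> short_term_sd * sqrt(2)
  rmssd <- vapply(1:20, function(s) {
    rr <- simulate_rr(rr_sim_params(mean_rr_ms = 900, short_term_sd_ms = 30,
                                    long_term_sd_ms = 0, duration_min = 60),
                      seed = s)
    hrv_time_domain(rr)$rmssd
  }, numeric(1))
  expect_equal(mean(rmssd), 30 * sqrt(2), tolerance = 0.1)
})

test_that("generator rejects degenerate parameters", {
  expect_error(rhythm_params(n_days = 0), "n_days")
  expect_error(rhythm_params(bed_start_h = 8, bed_end_h = 8), "zero length")
  expect_error(rhythm_params(fragmentation_p = 1.2), "probability")
  expect_error(rr_sim_params(duration_min = 0), "duration")
})

test_that("cohort simulation returns consistent subjects, truth and outcomes", {
  sim <- simulate_cohort(n_mi = 4, n_ctrl = 3, seed = 11)
  expect_equal(nrow(sim$subjects), 7)
  expect_equal(nrow(sim$cohort), 7)
  expect_equal(nrow(sim$truth), 7)
  expect_equal(sum(sim$cohort$group == "MI"), 4)
  # outcomes exist only in the patient stratum
  ctrl <- sim$cohort[sim$cohort$group == "control", ]
  expect_true(all(is.na(ctrl$readmission_days)))
  mi <- sim$cohort[sim$cohort$group == "MI", ]
  expect_true(all(mi$any_readmission %in% c(0, 1)))
  # mean readmission days is total/times when times > 0, else missing
  idx <- !is.na(mi$readmission_times) & mi$readmission_times > 0
  expect_equal(mi$mean_readmission_days[idx],
               mi$readmission_days[idx] / mi$readmission_times[idx])
  expect_true(all(is.na(mi$mean_readmission_days[!idx])))
  expect_identical(simulate_cohort(n_mi = 2, n_ctrl = 2, seed = 5)$cohort,
                   simulate_cohort(n_mi = 2, n_ctrl = 2, seed = 5)$cohort)
})

test_that("outcome models must reference known ground-truth indicators", {
  expect_error(
    outcome_model(list(bad = list(coef = c(nonexistent_thing = 1)))),
    "unknown indicator")
})

test_that("cohort files round-trip through the manifest formats", {
  sim <- simulate_cohort(
    n_mi = 2, n_ctrl = 2,
    mi = list(rhythm = rhythm_params(n_days = 4),
              rr = rr_sim_params(duration_min = 3)),
    ctrl = list(rhythm = rhythm_params(n_days = 4),
                rr = rr_sim_params(duration_min = 3)),
    jitter = jitter_spec(n_days_sd = 0), seed = 2)
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(sim, dir)
  manifest <- jsonlite::read_json(manifest_path)
  expect_length(manifest$subjects, 4)
  back <- read_epochs(file.path(dir, manifest$subjects[[1]]$activity_file))
  orig <- sim$subjects$activity[[1]]
  expect_equal(back$counts, as.numeric(orig$counts))
  expect_equal(back$in_bed, orig$in_bed)
  rr_back <- read_rr(file.path(dir, manifest$subjects[[1]]$rr_file))
  expect_equal(rr_back$rr_ms, sim$subjects$rr[[1]]$rr_ms, tolerance = 1e-8)
})
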