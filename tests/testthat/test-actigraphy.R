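write_epoch_csv <- function(counts, path, start = "2024-01-01 00:00:00",
                            drop_rows = integer()) {
  ep <- make_epochs(counts, start = start)
  if (length(drop_rows) > 0) ep <- ep[-drop_rows, ]
  readr::write_csv(
    data.frame(timestamp = format(ep$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               counts = ep$counts),
    path)
  path
}

test_that("read_epochs reads, validates and gap-fills the CSV dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(rep(5, 1440), f)
  ep <- read_epochs(f)
  expect_equal(nrow(ep), 1440)
  expect_true(all(ep$counts == 5))
  expect_false(any(ep$missing))

  # a 10-minute gap becomes 10 missing epochs
  write_epoch_csv(rep(5, 1440), f, drop_rows = 101:110)
  ep <- read_epochs(f)
  expect_equal(nrow(ep), 1440)
  expect_equal(sum(ep$missing), 10)
  expect_true(all(which(ep$missing) == 101:110))

  # invalid rows are reported with their position
  writeLines(c("timestamp,counts",
               "2024-01-01T00:00:00,5",
               "2024-01-01T00:01:00,-3"), f)
  expect_error(read_epochs(f), "negative counts.*2")
  writeLines(c("timestamp,counts",
               "2024-01-01T00:01:00,5",
               "2024-01-01T00:00:00,5"), f)
  expect_error(read_epochs(f), "non-monotone")
})

test_that("headerless two-column dialect is supported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2024-01-01T00:00:00,1", "2024-01-01T00:01:00,2"), f)
  ep <- read_epochs(f, dialect = "bare")
  expect_equal(ep$counts, c(1, 2))
})

test_that("hourly averaging and its missingness rule", {
  ep <- make_epochs(rep(7, 120))
  prof <- hourly_profile(ep)
  expect_equal(prof$activity, c(7, 7))

  ep <- make_epochs(0:59)
  expect_equal(hourly_profile(ep)$activity, 29.5)

  # an hour with more than half its epochs missing is flagged missing
  cnt <- rep(10, 120)
  cnt[1:40] <- NA
  prof <- hourly_profile(make_epochs(cnt))
  expect_true(prof$missing[1])
  expect_false(prof$missing[2])
  expect_true(is.na(prof$activity[1]))

  # exactly half missing is retained
  cnt[1:40] <- 10; cnt[1:30] <- NA
  expect_false(hourly_profile(make_epochs(cnt))$missing[1])
})

test_that("recording-length eligibility is inclusive at the boundary and monotone", {
  expect_false(eligible_for_circadian(make_epochs(rep(1, 2.5 * 1440))))
  expect_true(eligible_for_circadian(make_epochs(rep(1, 3 * 1440))))
  expect_true(eligible_for_circadian(make_epochs(rep(1, 5.75 * 1440))))
  lens <- c(1, 2, 2.9, 3, 4, 6) * 1440
  elig <- vapply(lens, function(n) eligible_for_circadian(make_epochs(rep(1, n))),
                 logical(1))
  expect_true(all(diff(as.integer(elig)) >= 0))
  # missing epochs do not count toward the span
  cnt <- rep(1, 3 * 1440); cnt[1:120] <- NA
  expect_false(eligible_for_circadian(make_epochs(cnt)))
})

test_that("day segmentation partitions the recording", {
  ep <- make_epochs(rep(1, 3 * 1440))
  seg <- segment_days(ep)
  expect_equal(unique(seg$day), 1:3)
  expect_true(all(seg$day_complete))

  seg <- segment_days(make_epochs(rep(1, 3.5 * 1440)))
  expect_equal(max(seg$day), 4)
  expect_false(any(seg$day_complete[seg$day == 4]))
  expect_equal(sum(table(seg$day)), nrow(seg))  # partition: no epoch lost

  # anchor at noon over two calendar days: one complete noon-to-noon block
  seg <- segment_days(make_epochs(rep(1, 2 * 1440)), day_anchor_h = 12)
  counts_by_day <- table(seg$day)
  expect_equal(length(counts_by_day), 3L)
  expect_equal(sum(as.numeric(counts_by_day) == 1440), 1L)
})

test_that("day/night activity statistics", {
  ep <- make_epochs(rep(50, 1440))
  s <- day_night_stats(ep)
  expect_equal(unlist(s), c(day_mean = 50, day_sd = 0, night_mean = 50, night_sd = 0))

  h <- clock_hours(make_epochs(rep(0, 1440))$time)
  cnt <- ifelse(h >= 6 & h < 22, 100, 0)
  s <- day_night_stats(make_epochs(cnt))
  expect_equal(unlist(s), c(day_mean = 100, day_sd = 0, night_mean = 0, night_sd = 0))

  # two-point day distribution, population SD convention
  cnt <- ifelse(h >= 6 & h < 22, rep(c(50, 150), length.out = 1440), 0)
  s <- day_night_stats(make_epochs(cnt), sd_type = "population")
  expect_equal(s$day_mean, 100)
  expect_equal(s$day_sd, 50)
})
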