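#' Hourly activity profile
#'
#' Averages minute epochs into clock-hour bins, the resolution at which the
#' nonparametric circadian indicators are defined. Each hourly value is the
#' arithmetic mean of the available (non-missing) epochs in that hour; hours
#' in which more than half of the epochs are missing are flagged missing and
#' excluded from indicator computation rather than imputed.
#'
#' @param epochs An epoch tibble (columns `time`, `counts`, optionally
#'   `missing`).
#' @return A tibble with one row per covered hour: `hour_start` (POSIXct),
#'   `date`, `hour` (0-23), `activity` (mean counts/min, NA when missing),
#'   `n` (epochs averaged) and `missing`.
#' @export
hourly_profile <- function(epochs) {
  assert_epochs(epochs)
  miss <- missing_mask(epochs)
  hour_key <- floor(as.numeric(epochs$time) / 3600)
  # the time grid is sorted, so each hour is a contiguous block
  blocks <- rle(hour_key)
  keys <- blocks$values
  ends <- cumsum(blocks$lengths)
  n_slots <- as.integer(blocks$lengths)
  ok <- !miss & !is.na(epochs$counts)
  block_sum <- function(x) diff(c(0, cumsum(x)[ends]))
  n_ok <- as.integer(block_sum(ok))
  sums <- block_sum(ifelse(ok, epochs$counts, 0))
  value <- ifelse(n_ok > 0, sums / n_ok, NA_real_)
  hour_missing <- (n_slots - n_ok) > n_slots / 2 | n_ok == 0L
  value[hour_missing] <- NA_real_
  hour_start <- as.POSIXct(keys * 3600, origin = "1970-01-01", tz = "UTC")
  out <- tibble::tibble(
    hour_start = hour_start,
    date = as.Date(hour_start, tz = "UTC"),
    hour = as.integer(keys %% 24),
    activity = value,
    n = n_ok,
    missing = hour_missing
  )
  class(out) <- c("hourly_profile", class(out))
  out
}

#' Recording-length eligibility for circadian analysis
#'
#' Recordings shorter than `min_days` of non-missing data are excluded from
#' circadian rhythm analysis (the indicators need several complete days to be
#' stable). The boundary is inclusive: exactly `min_days` passes.
#'
#' @param epochs An epoch tibble.
#' @param min_days Minimum recording length in days; default 3.
#' @return `TRUE` or `FALSE`.
#' @export
eligible_for_circadian <- function(epochs, min_days = 3) {
  assert_epochs(epochs)
  es <- epoch_seconds(epochs)
  sum(!missing_mask(epochs)) * es >= min_days * 86400
}

#' Segment a recording into consecutive 24-h day blocks
#'
#' Adds a day index and completeness flag to each epoch: day 1 starts at the
#' first grid point at or before the recording start whose clock time equals
#' `day_anchor_h`; a block is complete when the recording covers its full
#' 24 hours. Concatenating the blocks restores the series.
#'
#' @param epochs An epoch tibble.
#' @param day_anchor_h Clock hour at which days begin; default 0 (midnight).
#' @return The input tibble with added columns `day` (integer, 1-based) and
#'   `day_complete` (logical; TRUE for epochs of fully covered blocks).
#' @export
segment_days <- function(epochs, day_anchor_h = 0) {
  assert_epochs(epochs)
  es <- epoch_seconds(epochs)
  t0 <- as.numeric(epochs$time)
  anchor_off <- day_anchor_h * 3600
  day <- floor((t0 - anchor_off) / 86400)
  day <- day - min(day) + 1L
  per_day <- 86400 / es
  cover <- table(day)
  complete_days <- as.integer(names(cover))[as.numeric(cover) == per_day]
  epochs$day <- as.integer(day)
  epochs$day_complete <- epochs$day %in% complete_days
  epochs
}

#' Day and night activity statistics
#'
#' Mean and SD of epoch-level counts falling inside the daytime and
#' nighttime clock windows across the whole recording. The day/night split
#' is the main free parameter of these statistics; the defaults are
#' day `[06:00, 22:00)` and night `[22:00, 06:00)`.
#'
#' @param epochs An epoch tibble.
#' @param day_window,night_window Two clock hours `c(start, end)`, half-open,
#'   may wrap midnight; must be non-empty.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param per_day_means If `TRUE`, compute the statistics across per-day mean
#'   activity rather than across epochs.
#' @return A one-row tibble: `day_mean`, `day_sd`, `night_mean`, `night_sd`
#'   (counts/min).
#' @export
day_night_stats <- function(epochs, day_window = c(6, 22),
                            night_window = c(22, 6),
                            sd_type = c("sample", "population"),
                            per_day_means = FALSE) {
  assert_epochs(epochs)
  sd_type <- match.arg(sd_type)
  miss <- missing_mask(epochs)
  h <- clock_hours(epochs$time)
  sd_fun <- function(x) {
    if (length(x) < 2L) return(0)
    if (sd_type == "sample") sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  one_window <- function(window) {
    sel <- in_clock_window(h, window) & !miss
    if (!any(sel)) abort("clock window contains no epochs")
    x <- epochs$counts[sel]
    if (per_day_means) {
      d <- floor(as.numeric(epochs$time[sel]) / 86400)
      x <- as.numeric(tapply(x, d, mean))
    }
    c(mean(x), sd_fun(x))
  }
  d <- one_window(day_window)
  n <- one_window(night_window)
  tibble::tibble(day_mean = d[1], day_sd = d[2],
                 night_mean = n[1], night_sd = n[2])
}
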