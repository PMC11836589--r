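#' Score sleep/wake from minute-epoch activity
#'
#' Epoch-by-epoch sleep/wake classification resting on the observation that
#' there is less motion during sleep than during wakefulness: an epoch is
#' scored asleep when a weighted moving average of the surrounding activity
#' (a 7-epoch window spanning four epochs before to two after, in the style
#' of the Cole-Kripke actigraphy algorithm) falls below a threshold. Weights
#' are normalized to sum to one, so the threshold is in counts/min and must
#' be chosen for the device's count scale; matching any proprietary device
#' algorithm numerically is a non-goal.
#'
#' @param epochs An epoch tibble with 60-s epochs.
#' @param weights Seven window weights for lags -4..+2 (before
#'   normalization); default `c(106, 54, 58, 76, 230, 74, 67)`.
#' @param threshold Sleep threshold on the weighted mean, counts/min;
#'   default 40.
#' @return The input tibble with an added logical column `asleep` (missing
#'   epochs score `NA`).
#' @export
score_sleep_wake <- function(epochs,
                             weights = c(106, 54, 58, 76, 230, 74, 67),
                             threshold = 40) {
  assert_epochs(epochs)
  if (abs(epoch_seconds(epochs) - 60) > 1e-9) {
    abort("sleep scoring is defined for 60-s epochs only")
  }
  if (length(weights) != 7L || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be 7 non-negative values for lags -4..+2")
  }
  w <- weights / sum(weights)
  miss <- missing_mask(epochs)
  x <- ifelse(miss, NA_real_, epochs$counts)
  n <- length(x)
  # pad so edge epochs use the available part of the window
  xp <- c(rep(NA_real_, 4), x, rep(NA_real_, 2))
  num <- numeric(n)
  den <- numeric(n)
  for (k in seq_len(7L)) {
    xi <- xp[seq_len(n) + (k - 1L)]
    ok <- !is.na(xi)
    num[ok] <- num[ok] + w[k] * xi[ok]
    den <- den + w[k] * ok
  }
  score <- ifelse(den > 0, num / den, NA_real_)
  epochs$asleep <- score < threshold
  epochs$asleep[miss] <- NA
  epochs
}

# Maximal runs of a logical vector as (start, end) index pairs.
logical_runs <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(!is.na(r$values) & r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect the major nocturnal rest period
#'
#' For use when in-bed annotations are unavailable: finds, per day, the
#' longest sleep-dominated span. Consecutive sleep runs separated by wake
#' gaps of at most `max_gap_min` are bridged as long as the merged span
#' remains at least `min_frac` asleep; spans shorter than `min_len_h` hours
#' are discarded; each surviving span is assigned to the day of its
#' midpoint, keeping the longest per day.
#'
#' @param scored An epoch tibble with an `asleep` column
#'   (see [score_sleep_wake()]).
#' @param min_frac Minimum sleep fraction of a merged span; default 0.7.
#' @param max_gap_min Maximum bridgeable wake gap, minutes; default 60.
#' @param min_len_h Minimum span length, hours; default 3.
#' @return A tibble with columns `date`, `rest_start`, `rest_end`
#'   (half-open); zero rows if no day has a qualifying span.
#' @export
detect_major_rest <- function(scored, min_frac = 0.7, max_gap_min = 60,
                              min_len_h = 3) {
  assert_epochs(scored)
  if (!"asleep" %in% names(scored)) abort("`scored` must carry an `asleep` column")
  es <- epoch_seconds(scored)
  asleep <- scored$asleep
  asleep[is.na(asleep)] <- FALSE
  runs <- logical_runs(asleep)
  if (nrow(runs) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          rest_start = as.POSIXct(character(), tz = "UTC"),
                          rest_end = as.POSIXct(character(), tz = "UTC")))
  }
  max_gap <- max_gap_min * 60 / es
  # greedy left-to-right merge keeping the sleep fraction above min_frac
  merged <- list()
  cur <- runs[1, ]
  cur_sleep <- cur["end"] - cur["start"] + 1L
  if (nrow(runs) > 1L) for (i in 2:nrow(runs)) {
    gap <- runs[i, "start"] - cur["end"] - 1L
    cand_sleep <- cur_sleep + (runs[i, "end"] - runs[i, "start"] + 1L)
    cand_len <- runs[i, "end"] - cur["start"] + 1L
    if (gap <= max_gap && cand_sleep / cand_len >= min_frac) {
      cur["end"] <- runs[i, "end"]
      cur_sleep <- cand_sleep
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- runs[i, ]
      cur_sleep <- cur["end"] - cur["start"] + 1L
    }
  }
  merged[[length(merged) + 1L]] <- cur
  spans <- do.call(rbind, merged)
  len_h <- (spans[, "end"] - spans[, "start"] + 1L) * es / 3600
  spans <- spans[len_h >= min_len_h, , drop = FALSE]
  if (nrow(spans) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          rest_start = as.POSIXct(character(), tz = "UTC"),
                          rest_end = as.POSIXct(character(), tz = "UTC")))
  }
  rest_start <- scored$time[spans[, "start"]]
  rest_end <- scored$time[spans[, "end"]] + es
  mid <- rest_start + (as.numeric(rest_end) - as.numeric(rest_start)) / 2
  out <- tibble::tibble(date = as.Date(mid, tz = "UTC"),
                        rest_start = rest_start, rest_end = rest_end)
  out |>
    dplyr::mutate(len = as.numeric(.data$rest_end) - as.numeric(.data$rest_start)) |>
    dplyr::group_by(.data$date) |>
    dplyr::slice_max(.data$len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"len") |>
    dplyr::arrange(.data$rest_start)
}

#' Parametric sleep parameters per rest interval
#'
#' For each rest interval: sleep onset is the start of the first run of at
#' least `onset_min` consecutive sleep epochs; SOL (sleep onset latency) is
#' the time from rest start to onset; TST (total sleep time) the sleep
#' minutes and WASO (wake after sleep onset) the wake minutes between onset
#' and rest end; awakenings are the maximal wake runs of at least one epoch
#' after onset; SE (sleep efficiency) is TST over the rest-interval duration
#' in percent. By construction `SOL + TST + WASO` equals the rest duration.
#' If no onset run exists, the whole interval counts as latency
#' (`TST = WASO = 0`, `SE = 0`).
#'
#' @param scored An epoch tibble with `asleep` (see [score_sleep_wake()]).
#' @param rest A tibble of rest intervals (`rest_start`, `rest_end`), e.g.
#'   from [detect_major_rest()] or [read_bed_intervals()]; annotated bed
#'   intervals take precedence over detection by passing them here. When
#'   `NULL`, the `in_bed` annotation column is used if present, otherwise
#'   rest periods are detected with default settings.
#' @param onset_min Consecutive sleep minutes defining onset; default 10.
#' @return A tibble with one row per rest interval: `date`, `rest_min`,
#'   `sol_min`, `tst_min`, `waso_min`, `awakenings`, `se_pct`.
#' @export
sleep_parameters <- function(scored, rest = NULL, onset_min = 10) {
  assert_epochs(scored)
  if (!"asleep" %in% names(scored)) abort("`scored` must carry an `asleep` column")
  if (is.null(rest)) {
    rest <- bed_intervals_from_epochs(scored) %||% detect_major_rest(scored)
  }
  if (nrow(rest) == 0L) {
    warn("no rest intervals available; no sleep parameters computed")
    return(tibble::tibble(date = as.Date(character()), rest_min = numeric(),
                          sol_min = numeric(), tst_min = numeric(),
                          waso_min = numeric(), awakenings = integer(),
                          se_pct = numeric()))
  }
  es <- epoch_seconds(scored)
  per_min <- es / 60
  purrr::pmap_dfr(rest[, c("rest_start", "rest_end")],
                  function(rest_start, rest_end) {
    sel <- scored$time >= rest_start & scored$time < rest_end
    asleep <- scored$asleep[sel]
    asleep[is.na(asleep)] <- FALSE
    n <- length(asleep)
    date <- as.Date(rest_start + (as.numeric(rest_end) - as.numeric(rest_start)) / 2,
                    tz = "UTC")
    if (n == 0L) {
      warn("rest interval contains no epochs; skipped")
      return(NULL)
    }
    need <- max(1L, as.integer(ceiling(onset_min / per_min)))
    runs <- logical_runs(asleep)
    onset_runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= need, , drop = FALSE]
    rest_min <- n * per_min
    if (nrow(onset_runs) == 0L) {
      return(tibble::tibble(date = date, rest_min = rest_min, sol_min = rest_min,
                            tst_min = 0, waso_min = 0, awakenings = 0L,
                            se_pct = 0))
    }
    onset <- unname(onset_runs[1, "start"])
    sol <- (onset - 1L) * per_min
    span <- asleep[onset:n]
    tst <- sum(span) * per_min
    waso <- sum(!span) * per_min
    awakenings <- nrow(logical_runs(!span))
    tibble::tibble(date = date, rest_min = rest_min, sol_min = sol,
                   tst_min = tst, waso_min = waso,
                   awakenings = as.integer(awakenings),
                   se_pct = tst / rest_min * 100)
  })
}

#' Per-subject summary of nightly sleep parameters
#'
#' @param per_night Output of [sleep_parameters()].
#' @return A one-row tibble with the across-night means: `sol_min`,
#'   `tst_min`, `se_pct`, `waso_min`, `awakenings`, and `n_nights`.
#' @export
sleep_summary <- function(per_night) {
  tibble::tibble(
    sol_min = mean(per_night$sol_min),
    tst_min = mean(per_night$tst_min),
    se_pct = mean(per_night$se_pct),
    waso_min = mean(per_night$waso_min),
    awakenings = mean(per_night$awakenings),
    n_nights = nrow(per_night)
  )
}
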