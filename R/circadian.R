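# Circular sliding-window search over a 24-value daily profile.
# Returns max/min window means, their midpoints (start + width/2, mod 24),
# ties broken by earliest start hour; windows containing NA are skipped.
window_search <- function(values24, width) {
  stopifnot(length(values24) == 24L)
  means <- rep(NA_real_, 24L)
  ext <- c(values24, values24)
  for (s in 1:24) {
    w <- ext[s:(s + width - 1L)]
    if (!anyNA(w)) means[s] <- mean(w)
  }
  if (all(is.na(means))) return(NULL)
  i_max <- which.max(means)   # earliest start on ties
  i_min <- which.min(means)
  list(max_mean = means[i_max], max_mid = (i_max - 1 + width / 2) %% 24,
       min_mean = means[i_min], min_mid = (i_min - 1 + width / 2) %% 24)
}

# Non-missing hourly values of a profile, in time order.
profile_values <- function(profile) {
  if (!all(c("activity", "missing") %in% names(profile))) {
    abort("`profile` must come from hourly_profile()")
  }
  profile$activity[!profile$missing]
}

#' Interdaily stability (IS)
#'
#' The fraction of the total hourly-activity variance explained by the mean
#' 24-h profile:
#' \deqn{IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{24 \sum_i (x_i - \bar x)^2}}
#' over the \eqn{N} non-missing hourly values \eqn{x_i}, their 24 clock-hour
#' means \eqn{\bar x_h}, and the grand mean \eqn{\bar x}. IS is 1 for a
#' pattern repeated identically every day and 0 when clock hour carries no
#' information; lower values indicate a less stable rest-activity rhythm.
#'
#' @param profile An [hourly_profile()] tibble covering at least 3 days.
#' @return IS in `[0, 1]`.
#' @export
interdaily_stability <- function(profile) {
  ok <- !profile$missing
  x <- profile$activity[ok]
  hod <- profile$hour[ok]
  if (length(x) < 48L || length(unique(hod)) < 2L) {
    abort("IS needs several days of hourly values over distinct clock hours")
  }
  gm <- mean(x)
  tot <- sum((x - gm)^2)
  if (tot == 0) abort("IS is undefined for a zero-variance series")
  hm <- tapply(x, hod, mean)
  # clock-hour means enter once per distinct hour present
  length(x) * sum((hm - gm)^2) / (24 * tot)
}

#' Intradaily variability (IV)
#'
#' The normalized mean square of successive hourly differences:
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}{(N-1)\sum_i (x_i - \bar x)^2}}
#' Pairs spanning a missing hour are skipped with the denominator unchanged.
#' IV is near 2 for white noise, small for a smooth 24-h rhythm, and reaches
#' its algebraic maximum of 4 for an hourly alternating series; higher values
#' indicate a more fragmented rhythm.
#'
#' @param profile An [hourly_profile()] tibble with at least 25 consecutive
#'   hourly values.
#' @return IV (dimensionless, >= 0).
#' @export
intradaily_variability <- function(profile) {
  ok <- !profile$missing
  x <- profile$activity[ok]
  n <- length(x)
  if (n < 25L) abort("IV needs at least 25 hourly values")
  gm <- mean(x)
  tot <- sum((x - gm)^2)
  if (tot == 0) abort("IV is undefined for a zero-variance series")
  t_h <- as.numeric(profile$hour_start[ok]) / 3600
  adjacent <- diff(t_h) == 1
  d2 <- sum(diff(x)[adjacent]^2)
  n * d2 / ((n - 1) * tot)
}

#' M10 and L5: extremes of the daily activity profile
#'
#' For each complete day, slides windows of 10 and 5 consecutive hourly bins
#' (with circular wrap inside the 24-h block) to find the most active 10
#' hours (M10) and least active 5 hours (L5) and their central clock times
#' (midpoints). Per-day M10, L5 and relative amplitude are averaged
#' arithmetically across days; the midpoints are averaged circularly, since
#' naive averaging is unstable near the midnight wrap. Ties are broken by
#' the earliest window start. Days in which missing hours intersect every
#' candidate window are skipped.
#'
#' @param profile An [hourly_profile()] tibble.
#' @param day_anchor_h Clock hour at which day blocks begin; default 0.
#' @param average_profile If `TRUE`, search the single across-day mean 24-h
#'   profile instead of averaging per-day results.
#' @return A one-row tibble: `m10`, `midpoint_m10_h`, `l5`, `midpoint_l5_h`,
#'   `ra`, `n_days_used`.
#' @export
m10_l5 <- function(profile, day_anchor_h = 0, average_profile = FALSE) {
  ok_profile <- profile
  t_h <- as.numeric(profile$hour_start) / 3600
  day <- floor((t_h - day_anchor_h) / 24)
  day <- day - min(day) + 1L
  vals <- ifelse(profile$missing, NA_real_, profile$activity)
  hod_in_block <- as.integer((t_h - day_anchor_h) %% 24)

  if (average_profile) {
    mean_prof <- as.numeric(tapply(vals, hod_in_block, mean, na.rm = TRUE))
    if (length(mean_prof) < 24L || anyNA(mean_prof)) {
      abort("average profile does not cover all 24 clock hours")
    }
    w10 <- window_search(mean_prof, 10L)
    w5 <- window_search(mean_prof, 5L)
    return(tibble::tibble(
      m10 = w10$max_mean, midpoint_m10_h = (w10$max_mid + day_anchor_h) %% 24,
      l5 = w5$min_mean, midpoint_l5_h = (w5$min_mid + day_anchor_h) %% 24,
      ra = (w10$max_mean - w5$min_mean) / (w10$max_mean + w5$min_mean),
      n_days_used = length(unique(day))))
  }

  res <- list()
  for (d in unique(day)) {
    sel <- day == d
    if (sum(sel) != 24L) next  # incomplete block
    v <- vals[sel][order(hod_in_block[sel])]
    w10 <- window_search(v, 10L)
    w5 <- window_search(v, 5L)
    if (is.null(w10) || is.null(w5)) next
    res[[length(res) + 1L]] <- tibble::tibble(
      m10 = w10$max_mean, mid10 = (w10$max_mid + day_anchor_h) %% 24,
      l5 = w5$min_mean, mid5 = (w5$min_mid + day_anchor_h) %% 24,
      ra = if (w10$max_mean + w5$min_mean > 0)
        (w10$max_mean - w5$min_mean) / (w10$max_mean + w5$min_mean)
      else NA_real_)
  }
  if (length(res) == 0L) abort("no complete day available for M10/L5")
  per_day <- dplyr::bind_rows(res)
  tibble::tibble(
    m10 = mean(per_day$m10),
    midpoint_m10_h = circular_mean_hours(per_day$mid10),
    l5 = mean(per_day$l5),
    midpoint_l5_h = circular_mean_hours(per_day$mid5),
    ra = mean(per_day$ra, na.rm = TRUE),
    n_days_used = nrow(per_day)
  )
}

#' Relative amplitude (RA)
#'
#' The day-night activity contrast normalized to its mean level:
#' `(M10 - L5) / (M10 + L5)`, in `[0, 1]`; 1 when the least active 5 hours
#' are completely still.
#'
#' @param m10,l5 M10 and L5 values with `m10 >= l5 >= 0`.
#' @return RA.
#' @export
relative_amplitude <- function(m10, l5) {
  if (any(m10 + l5 <= 0)) abort("RA is undefined when M10 + L5 = 0")
  (m10 - l5) / (m10 + l5)
}

#' Actigraphic dichotomy index (I<O)
#'
#' The percentage of in-bed epochs whose activity falls strictly below the
#' median of the out-of-bed activity. Values near 100 indicate a sharp
#' rest-activity separation; lower values a weaker circadian rest-activity
#' rhythm. In-bed epochs are taken from `rest` intervals when given,
#' otherwise from the `in_bed` annotation column.
#'
#' @param epochs An epoch tibble.
#' @param rest Optional rest-interval tibble (`rest_start`, `rest_end`).
#' @return Percentage in `[0, 100]`.
#' @export
dichotomy_index <- function(epochs, rest = NULL) {
  assert_epochs(epochs)
  miss <- missing_mask(epochs)
  if (!is.null(rest)) {
    if (nrow(rest) == 0L) abort("no rest intervals: in-bed set is empty")
    in_bed <- rep(FALSE, nrow(epochs))
    for (i in seq_len(nrow(rest))) {
      in_bed <- in_bed | (epochs$time >= rest$rest_start[i] &
                            epochs$time < rest$rest_end[i])
    }
  } else if ("in_bed" %in% names(epochs)) {
    in_bed <- as.logical(epochs$in_bed)
  } else {
    abort("no in-bed information: pass `rest` or an `in_bed` column")
  }
  inb <- epochs$counts[in_bed & !miss]
  outb <- epochs$counts[!in_bed & !miss]
  if (length(inb) == 0L) abort("in-bed epoch set is empty")
  if (length(outb) == 0L) abort("out-of-bed epoch set is empty")
  100 * mean(inb < median(outb))
}

#' All nonparametric circadian indicators for one subject
#'
#' Convenience wrapper computing the full indicator set from one epoch
#' series: IS, IV, M10/L5 and their midpoints, relative amplitude, the
#' dichotomy index, and day/night activity means and SDs.
#'
#' @param epochs An epoch tibble.
#' @param rest Optional rest intervals for the dichotomy index; when `NULL`,
#'   in-bed annotations or detected major rest periods are used.
#' @param day_window,night_window Clock windows for [day_night_stats()].
#' @inheritParams m10_l5
#' @return A one-row tibble with columns `is`, `iv`, `m10`,
#'   `midpoint_m10_h`, `l5`, `midpoint_l5_h`, `ra`, `dichotomy_index`,
#'   `day_mean`, `day_sd`, `night_mean`, `night_sd`.
#' @export
circadian_indicators <- function(epochs, rest = NULL, day_window = c(6, 22),
                                 night_window = c(22, 6), day_anchor_h = 0) {
  assert_epochs(epochs)
  prof <- hourly_profile(epochs)
  ml <- m10_l5(prof, day_anchor_h = day_anchor_h)
  if (is.null(rest) && !("in_bed" %in% names(epochs))) {
    scored <- score_sleep_wake(epochs)
    rest <- detect_major_rest(scored)
  }
  di <- dichotomy_index(epochs, rest = rest)
  dn <- day_night_stats(epochs, day_window = day_window,
                        night_window = night_window)
  tibble::tibble(
    is = interdaily_stability(prof),
    iv = intradaily_variability(prof),
    m10 = ml$m10, midpoint_m10_h = ml$midpoint_m10_h,
    l5 = ml$l5, midpoint_l5_h = ml$midpoint_l5_h,
    ra = ml$ra, dichotomy_index = di
  ) |>
    dplyr::bind_cols(dn)
}
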