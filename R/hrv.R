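# Indices of adjacent valid RR pairs; differences rr[i+1] - rr[i].
valid_pair_diffs <- function(rr_ms, valid) {
  i <- which(valid[-length(valid)] & valid[-1])
  rr_ms[i + 1L] - rr_ms[i]
}

#' Clean an RR-interval series
#'
#' Masks physiologically implausible intervals and artefact jumps: an
#' interval is invalid when it lies outside `bounds` or differs from the
#' previous valid interval by more than `max_rel_change` relative change.
#' Successive-difference metrics downstream use only adjacent valid pairs.
#'
#' @param rr A tibble with column `rr_ms` (or a numeric vector).
#' @param bounds Plausible interval range in ms; default `c(300, 2000)`.
#' @param max_rel_change Maximum relative change between consecutive valid
#'   intervals; default 0.2.
#' @return A tibble with columns `rr_ms` and `valid`.
#' @export
clean_rr <- function(rr, bounds = c(300, 2000), max_rel_change = 0.2) {
  rr_ms <- if (is.data.frame(rr)) rr$rr_ms else as.numeric(rr)
  if (length(rr_ms) == 0L) abort("empty RR series")
  n <- length(rr_ms)
  valid <- rr_ms >= bounds[1] & rr_ms <= bounds[2]
  # fast path: when every interval is in bounds and every consecutive change
  # is within tolerance, the sequential rule cannot mask anything
  if (all(valid) &&
      all(abs(diff(rr_ms)) <= max_rel_change * rr_ms[-n])) {
    return(tibble::tibble(rr_ms = rr_ms, valid = valid))
  }
  last_valid <- NA_real_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(last_valid) &&
        abs(rr_ms[i] - last_valid) > max_rel_change * last_valid) {
      valid[i] <- FALSE
    } else {
      last_valid <- rr_ms[i]
    }
  }
  if (sum(valid) < 2L) abort("fewer than 2 valid RR intervals after cleaning")
  tibble::tibble(rr_ms = rr_ms, valid = valid)
}

#' Time-domain HRV metrics
#'
#' Over the valid intervals: mean RR, heart rate (`60000 / mean RR`), SDRR
#' (sample SD of RR), RMSSD (root mean square of successive differences over
#' adjacent valid pairs), and pNN50/pNN20 (percentage of successive
#' differences strictly exceeding 50/20 ms in absolute value).
#'
#' @param rr A cleaned tibble from [clean_rr()] (a plain `rr_ms`
#'   tibble/vector is treated as all-valid).
#' @return A one-row tibble: `mean_rr`, `hr`, `sdrr`, `rmssd`, `pnn50`,
#'   `pnn20`, `n_valid`.
#' @export
hrv_time_domain <- function(rr) {
  rr <- as_clean_rr(rr)
  x <- rr$rr_ms[rr$valid]
  if (length(x) < 2L) abort("need at least 2 valid RR intervals")
  d <- valid_pair_diffs(rr$rr_ms, rr$valid)
  if (length(d) == 0L) abort("no adjacent valid RR pairs; difference metrics undefined")
  tibble::tibble(
    mean_rr = mean(x),
    hr = 60000 / mean(x),
    sdrr = sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    pnn20 = 100 * mean(abs(d) > 20),
    n_valid = length(x)
  )
}

#' Poincare plot dispersion (SD1, SD2)
#'
#' SD1 is the dispersion of the lag-1 Poincare scatter perpendicular to the
#' line of identity and reflects short-term (parasympathetic) variability;
#' SD2 the dispersion along it. Computed by the successive-difference
#' algebra with sample (n-1) variances:
#' `SD1 = sqrt(Var(dRR) / 2)`, `SD2 = sqrt(2 SDRR^2 - Var(dRR) / 2)`,
#' which satisfies `SDRR^2 = (SD1^2 + SD2^2) / 2`.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble: `sd1`, `sd2`, `sd_ratio` (= SD1/SD2).
#' @export
hrv_poincare <- function(rr) {
  rr <- as_clean_rr(rr)
  x <- rr$rr_ms[rr$valid]
  if (length(x) < 3L) abort("need at least 3 valid RR intervals")
  d <- valid_pair_diffs(rr$rr_ms, rr$valid)
  if (length(d) < 2L) abort("need at least 2 adjacent valid RR pairs")
  vd <- var(d)
  sdrr2 <- var(x)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(0, 2 * sdrr2 - vd / 2))
  if (sd2 == 0) abort("SD2 = 0: SD ratio undefined")
  tibble::tibble(sd1 = sd1, sd2 = sd2, sd_ratio = sd1 / sd2)
}

#' Deceleration capacity of heart rate (DC)
#'
#' Phase-rectified signal averaging over deceleration anchors. Anchors are
#' intervals longer than their predecessor but by no more than
#' `anchor_filter` relative increase (excluding artefactual jumps); for each
#' anchor the segment `RR[i-L] .. RR[i+L-1]` (for `L = 2`: positions -2..1
#' relative to the anchor) is extracted, segments are averaged into the
#' phase-rectified signal `X(-L..L-1)`, and
#' `DC = (X(0) + X(1) - X(-1) - X(-2)) / 4`.
#' Only anchors whose full segment is valid contribute.
#'
#' @inheritParams hrv_time_domain
#' @param L Segment half-length; default 2 (the standard choice).
#' @param anchor_filter Maximum relative RR increase at an anchor;
#'   default 0.05.
#' @return DC in ms.
#' @export
deceleration_capacity <- function(rr, L = 2, anchor_filter = 0.05) {
  rr <- as_clean_rr(rr)
  x <- rr$rr_ms
  valid <- rr$valid
  n <- length(x)
  if (sum(valid) < 2L * L + 1L) abort("too few valid intervals for DC")
  cand <- seq_len(n)[seq_len(n) > L & seq_len(n) <= n - L + 1L]
  cum_bad <- cumsum(!valid)
  seg_ok <- (cum_bad[cand + L - 1L] - c(0, cum_bad)[cand - L]) == 0L
  up <- x[cand] > x[cand - 1L] & x[cand] <= (1 + anchor_filter) * x[cand - 1L]
  anchors <- cand[seg_ok & up]
  if (length(anchors) == 0L) {
    abort("no deceleration anchors found; DC undefined")
  }
  offsets <- (-L):(L - 1L)
  X <- vapply(offsets, function(o) mean(x[anchors + o]), numeric(1))
  names(X) <- offsets
  unname((X["0"] + X["1"] - X["-1"] - X["-2"]) / 4)
}

#' Full HRV indicator set for one recording
#'
#' Cleans the series and computes the time-domain, Poincare and deceleration
#' capacity metrics in one call. DC is `NA` (with a warning) when the series
#' has no deceleration anchors.
#'
#' @param rr A tibble with `rr_ms` (raw) or a numeric vector.
#' @param bounds,max_rel_change Cleaning parameters, see [clean_rr()].
#' @return A one-row tibble: `mean_rr`, `hr`, `sdrr`, `rmssd`, `pnn50`,
#'   `pnn20`, `sd1`, `sd2`, `sd_ratio`, `dc`, `n_valid`, `duration_min`.
#' @export
hrv_indicators <- function(rr, bounds = c(300, 2000), max_rel_change = 0.2) {
  cleaned <- clean_rr(rr, bounds = bounds, max_rel_change = max_rel_change)
  td <- hrv_time_domain(cleaned)
  pc <- hrv_poincare(cleaned)
  dc <- tryCatch(deceleration_capacity(cleaned), error = function(e) {
    warn(sprintf("DC undefined: %s", conditionMessage(e)))
    NA_real_
  })
  dplyr::bind_cols(td[, c("mean_rr", "hr", "sdrr", "rmssd", "pnn50", "pnn20")],
                   pc) |>
    dplyr::mutate(dc = dc, n_valid = td$n_valid,
                  duration_min = sum(cleaned$rr_ms) / 60000)
}

# Coerce vectors / raw tibbles to the cleaned representation (all valid).
as_clean_rr <- function(rr) {
  if (is.data.frame(rr) && all(c("rr_ms", "valid") %in% names(rr))) return(rr)
  rr_ms <- if (is.data.frame(rr)) rr$rr_ms else as.numeric(rr)
  tibble::tibble(rr_ms = rr_ms, valid = rep(TRUE, length(rr_ms)))
}
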