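# Build a minute-epoch tibble from a counts vector.
make_epochs <- function(counts, start = "2024-01-01 00:00:00", epoch_s = 60,
                        in_bed = NULL, missing = NULL) {
  start <- as.POSIXct(start, tz = "UTC")
  n <- length(counts)
  out <- tibble::tibble(
    time = start + (seq_len(n) - 1) * epoch_s,
    counts = counts,
    missing = missing %||% is.na(counts)
  )
  if (!is.null(in_bed)) out$in_bed <- in_bed
  structure(out, epoch_s = epoch_s, class = c("epoch_series", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an hourly-profile tibble directly from hourly values (NA = missing).
make_profile <- function(values, start = "2024-01-01 00:00:00") {
  start <- as.POSIXct(start, tz = "UTC")
  n <- length(values)
  hour_start <- start + (seq_len(n) - 1) * 3600
  out <- tibble::tibble(
    hour_start = hour_start,
    date = as.Date(hour_start, tz = "UTC"),
    hour = as.integer((as.numeric(hour_start) %/% 3600) %% 24),
    activity = values,
    n = ifelse(is.na(values), 0L, 60L),
    missing = is.na(values)
  )
  class(out) <- c("hourly_profile", class(out))
  out
}

# Epoch series whose diffs have exactly zero mean (for SD1 = RMSSD/sqrt(2)).
zero_mean_diff_rr <- function(n, seed) {
  withr::with_seed(seed, {
    d <- rnorm(n - 1, 0, 30)
    d <- d - mean(d)
    800 + c(0, cumsum(d))
  })
}
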