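#' @importFrom rlang abort warn .data :=
#' @importFrom stats sd var cor lm qnorm quantile rnorm runif rbinom median
#'   pt complete.cases coef
NULL

# Fractional clock hour in [0, 24) of POSIXct times (UTC arithmetic).
clock_hours <- function(t) {
  (as.numeric(t) %% 86400) / 3600
}

# Is clock hour h inside the half-open window [w[1], w[2]), wrapping midnight?
in_clock_window <- function(h, window) {
  if (length(window) != 2L || anyNA(window)) {
    abort("`window` must be two clock hours c(start, end).")
  }
  a <- window[1] %% 24
  b <- window[2] %% 24
  if (a == b) abort("clock window has zero length")
  if (a < b) h >= a & h < b else h >= a | h < b
}

# Seconds per epoch, from attribute or the time grid.
epoch_seconds <- function(epochs) {
  es <- attr(epochs, "epoch_s")
  if (!is.null(es)) return(as.numeric(es))
  if (nrow(epochs) < 2L) return(60)
  as.numeric(median(diff(as.numeric(epochs$time))))
}

assert_epochs <- function(epochs, arg = "epochs") {
  if (!is.data.frame(epochs) || !all(c("time", "counts") %in% names(epochs))) {
    abort(sprintf("`%s` must be a data frame with columns `time` and `counts`.", arg))
  }
  if (nrow(epochs) == 0L) abort(sprintf("`%s` has no rows.", arg))
  invisible(epochs)
}

# Missing-epoch indicator (FALSE everywhere when no mask is carried).
missing_mask <- function(epochs) {
  if ("missing" %in% names(epochs)) epochs$missing | is.na(epochs$counts)
  else is.na(epochs$counts)
}

# Circular mean of clock hours, NA-safe; returns value in [0, 24).
circular_mean_hours <- function(h, na.rm = TRUE) {
  if (na.rm) h <- h[!is.na(h)]
  if (length(h) == 0L) return(NA_real_)
  ang <- h / 24 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * 24
  m %% 24
}

# Derive a per-unit sub-seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
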