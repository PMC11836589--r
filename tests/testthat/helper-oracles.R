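# Naive reference implementations, written as direct transcriptions of the
# indicator definitions with explicit loops; deliberately independent of the
# package's vectorized code paths.

is_ref <- function(values, hour_of_day) {
  gm <- mean(values)
  num <- 0
  for (h in 0:23) {
    sel <- hour_of_day == h
    if (any(sel)) num <- num + (mean(values[sel]) - gm)^2
  }
  den <- 0
  for (v in values) den <- den + (v - gm)^2
  length(values) * num / (24 * den)
}

iv_ref <- function(values, adjacent = rep(TRUE, length(values) - 1)) {
  gm <- mean(values)
  num <- 0
  for (i in 2:length(values)) {
    if (adjacent[i - 1]) num <- num + (values[i] - values[i - 1])^2
  }
  den <- 0
  for (v in values) den <- den + (v - gm)^2
  n <- length(values)
  n * num / ((n - 1) * den)
}

# Exhaustive circular window search over a 24-h day.
m10_l5_ref <- function(v24, width) {
  best_max <- -Inf; best_min <- Inf; arg_max <- NA; arg_min <- NA
  for (s in 0:23) {
    idx <- ((s + 0:(width - 1)) %% 24) + 1
    if (anyNA(v24[idx])) next
    m <- mean(v24[idx])
    if (m > best_max) { best_max <- m; arg_max <- s }
    if (m < best_min) { best_min <- m; arg_min <- s }
  }
  list(max_mean = best_max, max_mid = (arg_max + width / 2) %% 24,
       min_mean = best_min, min_mid = (arg_min + width / 2) %% 24)
}

# Poincare dispersion transcribed from the definition used by the package
# (successive-difference algebra, sample variances) with explicit loops.
poincare_ref <- function(x) {
  n <- length(x)
  d <- numeric(n - 1)
  for (i in 1:(n - 1)) d[i] <- x[i + 1] - x[i]
  mv <- function(v) {
    m <- sum(v) / length(v)
    s <- 0
    for (vi in v) s <- s + (vi - m)^2
    s / (length(v) - 1)
  }
  sd1 <- sqrt(mv(d) / 2)
  sd2 <- sqrt(2 * mv(x) - mv(d) / 2)
  list(sd1 = sd1, sd2 = sd2)
}

# Rotated-coordinate Poincare scatter (the geometric picture).
poincare_geometric_ref <- function(x) {
  a <- x[-length(x)]
  b <- x[-1]
  list(sd1 = stats::sd((b - a) / sqrt(2)), sd2 = stats::sd((b + a) / sqrt(2)))
}

dc_ref <- function(x, L = 2, anchor_filter = 0.05) {
  n <- length(x)
  anchors <- c()
  for (i in seq_len(n)) {
    if (i <= L || i > n - L + 1) next
    if (x[i] > x[i - 1] && x[i] <= (1 + anchor_filter) * x[i - 1]) {
      anchors <- c(anchors, i)
    }
  }
  if (length(anchors) == 0) return(NULL)
  X <- sapply(-L:(L - 1), function(o) mean(x[anchors + o]))
  names(X) <- -L:(L - 1)
  (X["0"] + X["1"] - X["-1"] - X["-2"]) / 4
}
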