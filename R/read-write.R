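#' Read a minute-epoch actigraphy CSV
#'
#' Reads the package's actigraphy dialect: a header row
#' `timestamp,counts[,in_bed]` with ISO-8601 timestamps and one row per
#' epoch, or a headerless two-column `timestamp,counts` variant
#' (`dialect = "bare"`). Timestamps must be strictly increasing and on a
#' regular grid; interior gaps are filled with missing epochs
#' (`missing = TRUE`, `counts = NA`). Epoch timestamps mark the start of
#' each epoch; all intervals are half-open `[start, end)`.
#'
#' @param path Path to the CSV file.
#' @param dialect `"headered"` (default) or `"bare"`.
#' @param subject_id Optional subject identifier stored as an attribute;
#'   defaults to the file name without extension.
#' @param tz Time zone for parsing; default UTC.
#' @return A tibble of class `epoch_series` with columns `time`, `counts`,
#'   `in_bed` (if present) and `missing`.
#' @export
read_epochs <- function(path, dialect = c("headered", "bare"),
                        subject_id = NULL, tz = "UTC") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "headered") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    if (!all(c("timestamp", "counts") %in% names(raw))) {
      abort(sprintf("%s: expected columns `timestamp,counts[,in_bed]`", path))
    }
  } else {
    raw <- readr::read_csv(path, col_names = c("timestamp", "counts"),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  }
  time <- lubridate::ymd_hms(raw$timestamp, tz = tz, quiet = TRUE)
  bad_time <- which(is.na(time))
  if (length(bad_time) > 0L) {
    abort(sprintf("%s: unparseable timestamp at data row(s) %s", path,
                  paste(utils::head(bad_time, 5), collapse = ", ")))
  }
  counts <- suppressWarnings(as.numeric(raw$counts))
  bad_cnt <- which(is.na(counts) & !is.na(raw$counts))
  if (length(bad_cnt) > 0L) {
    abort(sprintf("%s: unparseable counts at data row(s) %s", path,
                  paste(utils::head(bad_cnt, 5), collapse = ", ")))
  }
  neg <- which(counts < 0)
  if (length(neg) > 0L) {
    abort(sprintf("%s: negative counts at data row(s) %s", path,
                  paste(utils::head(neg, 5), collapse = ", ")))
  }
  dt <- diff(as.numeric(time))
  nonmono <- which(dt <= 0)
  if (length(nonmono) > 0L) {
    abort(sprintf("%s: non-monotone timestamps at data row(s) %s", path,
                  paste(utils::head(nonmono + 1L, 5), collapse = ", ")))
  }
  epoch_s <- if (length(dt) > 0) min(dt) else 60
  in_bed <- if ("in_bed" %in% names(raw)) {
    raw$in_bed %in% c("1", "TRUE", "true", "T")
  } else NULL

  # regularize onto the epoch grid; gaps become missing epochs
  grid <- seq(time[1], time[length(time)], by = epoch_s)
  idx <- match(as.numeric(time), as.numeric(grid))
  if (anyNA(idx)) {
    abort(sprintf("%s: timestamps are not on a regular %ds grid", path, epoch_s))
  }
  out <- tibble::tibble(
    time = grid,
    counts = NA_real_,
    missing = TRUE
  )
  out$counts[idx] <- counts
  out$missing[idx] <- FALSE
  if (!is.null(in_bed)) {
    out$in_bed <- FALSE
    out$in_bed[idx] <- in_bed
    out <- out[, c("time", "counts", "in_bed", "missing")]
  }
  structure(out, epoch_s = epoch_s,
            subject_id = subject_id %||% sub("\\.[^.]+$", "", basename(path)),
            class = c("epoch_series", class(out)))
}

#' Write a minute-epoch actigraphy CSV
#'
#' Inverse of [read_epochs()] for the headered dialect. Missing epochs are
#' omitted from the file (they reappear as gap-filled missing rows on read).
#'
#' @param epochs An epoch tibble with columns `time`, `counts` and optionally
#'   `in_bed`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  assert_epochs(epochs)
  keep <- !missing_mask(epochs)
  out <- tibble::tibble(
    timestamp = format(epochs$time[keep], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    counts = epochs$counts[keep]
  )
  if ("in_bed" %in% names(epochs)) out$in_bed <- as.integer(epochs$in_bed[keep])
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an RR-interval file
#'
#' Accepts either one interval (ms) per line, or a CSV with header
#' `timestamp,rr_ms` (the timestamp column is ignored for analysis).
#'
#' @param path Path to the file.
#' @return A tibble with column `rr_ms`.
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (grepl("rr_ms", first, fixed = TRUE)) {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    rr <- as.numeric(raw$rr_ms)
  } else {
    rr <- suppressWarnings(as.numeric(readLines(path)))
  }
  bad <- which(is.na(rr) | rr <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-positive or unparseable RR at line(s) %s", path,
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  tibble::tibble(rr_ms = rr)
}

#' Read a sidecar file of in-bed intervals
#'
#' CSV with header `date,bed_start,bed_end`, where `bed_start`/`bed_end` are
#' ISO-8601 timestamps. Used to override algorithmic rest detection.
#'
#' @param path Path to the CSV file.
#' @param tz Time zone; default UTC.
#' @return A tibble with columns `rest_start` and `rest_end`.
#' @export
read_bed_intervals <- function(path, tz = "UTC") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("bed_start", "bed_end") %in% names(raw))) {
    abort(sprintf("%s: expected columns `date,bed_start,bed_end`", path))
  }
  out <- tibble::tibble(
    rest_start = lubridate::ymd_hms(raw$bed_start, tz = tz, quiet = TRUE),
    rest_end = lubridate::ymd_hms(raw$bed_end, tz = tz, quiet = TRUE)
  )
  if (anyNA(out$rest_start) || anyNA(out$rest_end) ||
      any(out$rest_end <= out$rest_start)) {
    abort(sprintf("%s: unparseable or non-positive bed intervals", path))
  }
  out
}

# Bed intervals carried as an `in_bed` epoch column, as [start, end) runs.
bed_intervals_from_epochs <- function(epochs) {
  if (!"in_bed" %in% names(epochs)) return(NULL)
  es <- epoch_seconds(epochs)
  r <- rle(as.logical(epochs$in_bed))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(NULL)
  tibble::tibble(
    rest_start = epochs$time[starts[keep]],
    rest_end = epochs$time[ends[keep]] + es
  )
}
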