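#' Double-plotted actogram
#'
#' The standard raster display of a multi-day actigraphy recording: one row
#' per day, 48 h wide so that each night appears twice and sleep timing can
#' be read across rows.
#'
#' @param epochs An epoch tibble.
#' @param max_count Counts at which the fill saturates; default the 98th
#'   percentile.
#' @return A ggplot object.
#' @export
plot_actogram <- function(epochs, max_count = NULL) {
  assert_epochs(epochs)
  miss <- missing_mask(epochs)
  df <- tibble::tibble(
    h = clock_hours(epochs$time),
    day = floor(as.numeric(epochs$time) / 86400),
    counts = ifelse(miss, NA_real_, epochs$counts)
  )
  df$day <- df$day - min(df$day) + 1
  second <- dplyr::mutate(df, h = .data$h + 24, day = .data$day - 1)
  df <- dplyr::bind_rows(df, second[second$day >= 1, ])
  cap <- max_count %||% stats::quantile(df$counts, 0.98, na.rm = TRUE)
  df$counts <- pmin(df$counts, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$day,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = unique(df$day)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 6),
                                labels = seq(0, 48, 6) %% 24) +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "Clock hour", y = "Day", fill = "Counts/min") +
    ggplot2::theme_minimal()
}

#' Mean 24-h activity profile
#'
#' Hourly activity averaged by clock hour across days, with the per-hour
#' spread across days as a ribbon.
#'
#' @param profile An [hourly_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_daily_profile <- function(profile) {
  df <- profile[!profile$missing, ] |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mean_act = mean(.data$activity),
                     sd_act = sd(.data$activity), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$mean_act)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_act - .data$sd_act),
      ymax = .data$mean_act + .data$sd_act), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Clock hour", y = "Activity (counts/min)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_daily_profile
#' @param object An [hourly_profile()] tibble.
#' @param ... Unused.
#' @method autoplot hourly_profile
#' @export
autoplot.hourly_profile <- function(object, ...) plot_daily_profile(object)

#' Poincare plot of an RR series
#'
#' Lag-1 scatter of successive RR intervals with the identity line; the
#' dispersion perpendicular to and along the line corresponds to SD1 and
#' SD2.
#'
#' @param rr A cleaned RR tibble (see [clean_rr()]) or numeric vector.
#' @return A ggplot object.
#' @export
plot_poincare <- function(rr) {
  rr <- as_clean_rr(rr)
  x <- rr$rr_ms[rr$valid]
  df <- tibble::tibble(rr_n = x[-length(x)], rr_n1 = x[-1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr_n, y = .data$rr_n1)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "RR(n) [ms]", y = "RR(n+1) [ms]") +
    ggplot2::theme_minimal()
}
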