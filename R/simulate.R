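#' Simulate a minute-epoch activity recording
#'
#' Generates one subject's actigraphy series from a [rhythm_params()]
#' description: a clipped 24-h cosine plus period-specific Gaussian noise,
#' with per-epoch fragmentation swaps (a fragmented epoch takes a draw from
#' the opposite period: the antiphase clock time with the other period's
#' noise SD). Counts are clipped at zero and then rounded to integers, as
#' devices report integer counts. The bed window is recorded in the `in_bed`
#' column.
#'
#' @param params A [rhythm_params()] object.
#' @param seed Integer seed; the same seed and parameters give an identical
#'   series.
#' @param start Start timestamp (coerced to POSIXct, UTC); default midnight
#'   2024-01-01.
#' @return A tibble of class `epoch_series` with columns `time`, `counts`,
#'   `in_bed` and `missing`, one row per epoch.
#' @examples
#' act <- simulate_activity(rhythm_params(n_days = 3), seed = 1)
#' @export
simulate_activity <- function(params, seed,
                              start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (!inherits(params, "rhythm_params")) params <- do.call(rhythm_params, params)
  start <- lubridate::as_datetime(start, tz = "UTC")
  per_day <- 86400 %/% params$epoch_s
  n <- params$n_days * per_day
  time <- start + seq_len(n) * params$epoch_s - params$epoch_s
  h <- clock_hours(time)
  night <- in_clock_window(h, c(params$bed_start_h, params$bed_end_h))

  cosine_at <- function(hh) {
    params$mesor + params$amplitude * cos(2 * pi * (hh - params$acrophase_h) / 24)
  }
  withr::with_seed(as.integer(seed), {
    noise_sd <- ifelse(night, params$night_noise_sd, params$day_noise_sd)
    value <- cosine_at(h) + rnorm(n, 0, 1) * noise_sd
    swap <- runif(n) < params$fragmentation_p
    if (any(swap)) {
      opp_sd <- ifelse(night[swap], params$day_noise_sd, params$night_noise_sd)
      value[swap] <- cosine_at((h[swap] + 12) %% 24) + rnorm(sum(swap), 0, 1) * opp_sd
    }
  })
  counts <- round(pmax(0, value))
  out <- tibble::tibble(time = time, counts = as.integer(counts),
                        in_bed = night, missing = FALSE)
  structure(out, epoch_s = params$epoch_s,
            class = c("epoch_series", class(out)))
}

#' Simulate an RR-interval series
#'
#' RR intervals are the subject mean plus a white beat-to-beat component
#' (SD `short_term_sd_ms`, so successive differences have SD
#' `short_term_sd_ms * sqrt(2)`) plus a slow AR(1) drift with stationary SD
#' `long_term_sd_ms` (autoregressive coefficient 0.995 per beat). The series
#' is truncated once its cumulative sum covers `duration_min` and clipped to
#' stay positive.
#'
#' @param params A [rr_sim_params()] object.
#' @param seed Integer seed.
#' @return A tibble with column `rr_ms`.
#' @examples
#' rr <- simulate_rr(rr_sim_params(duration_min = 5), seed = 1)
#' @export
simulate_rr <- function(params, seed) {
  if (!inherits(params, "rr_sim_params")) params <- do.call(rr_sim_params, params)
  total_ms <- params$duration_min * 60000
  n <- ceiling(total_ms / params$mean_rr_ms * 1.2) + 10L
  phi <- 0.995
  withr::with_seed(as.integer(seed), {
    white <- rnorm(n, 0, params$short_term_sd_ms)
    drift <- if (params$long_term_sd_ms > 0) {
      innov <- rnorm(n, 0, params$long_term_sd_ms * sqrt(1 - phi^2))
      as.numeric(stats::filter(innov, phi, method = "recursive",
                               init = rnorm(1, 0, params$long_term_sd_ms)))
    } else {
      numeric(n)
    }
  })
  rr <- pmax(params$mean_rr_ms + white + drift, 1)
  keep <- which(cumsum(rr) >= total_ms)
  if (length(keep) > 0L) rr <- rr[seq_len(keep[1])]
  tibble::tibble(rr_ms = rr)
}

# Noise-free ground-truth indicator values implied by one subject's
# parameters; used only by outcome generation and recovery tests.
truth_indicators <- function(rhythm, rr) {
  h_min <- (seq_len(1440) - 1) / 60
  v <- pmax(0, rhythm$mesor +
              rhythm$amplitude * cos(2 * pi * (h_min - rhythm$acrophase_h) / 24))
  night <- in_clock_window(h_min, c(rhythm$bed_start_h, rhythm$bed_end_h))
  hourly <- as.numeric(rowsum(v, rep(0:23, each = 60))) / 60
  w10 <- window_search(hourly, 10L)
  w5 <- window_search(hourly, 5L)
  sdrr <- sqrt(rr$short_term_sd_ms^2 + rr$long_term_sd_ms^2)
  sd1 <- rr$short_term_sd_ms
  sd2 <- sqrt(rr$short_term_sd_ms^2 + 2 * rr$long_term_sd_ms^2)
  tibble::tibble(
    day_mean = mean(v[!night]), night_mean = mean(v[night]),
    m10 = w10$max_mean, midpoint_m10_h = w10$max_mid,
    l5 = w5$min_mean, midpoint_l5_h = w5$min_mid,
    ra = (w10$max_mean - w5$min_mean) / (w10$max_mean + w5$min_mean),
    mean_rr = rr$mean_rr_ms, sdrr = sdrr,
    rmssd = rr$short_term_sd_ms * sqrt(2),
    sd1 = sd1, sd2 = sd2, sd_ratio = sd1 / sd2
  )
}

# Apply jitter_spec to a group template, one subject.
jitter_template <- function(template, jit) {
  r <- template$rhythm
  q <- template$rr
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  r$mesor <- r$mesor * exp(rnorm(1, 0, jit$mesor_sdlog))
  r$amplitude <- r$amplitude * exp(rnorm(1, 0, jit$amplitude_sdlog))
  r$acrophase_h <- (r$acrophase_h + rnorm(1, 0, jit$acrophase_sd_h)) %% 24
  if (r$fragmentation_p > 0 && r$fragmentation_p < 1 && jit$frag_sdlogit > 0) {
    r$fragmentation_p <- inv_logit(logit(r$fragmentation_p) +
                                     rnorm(1, 0, jit$frag_sdlogit))
  }
  r$day_noise_sd <- r$day_noise_sd * exp(rnorm(1, 0, jit$noise_sdlog))
  r$night_noise_sd <- r$night_noise_sd * exp(rnorm(1, 0, jit$noise_sdlog))
  r$n_days <- max(1L, as.integer(round(r$n_days + rnorm(1, 0, jit$n_days_sd))))
  q$mean_rr_ms <- max(300, q$mean_rr_ms + rnorm(1, 0, jit$rr_mean_sd))
  q$short_term_sd_ms <- q$short_term_sd_ms * exp(rnorm(1, 0, jit$rr_sd_sdlog))
  q$long_term_sd_ms <- q$long_term_sd_ms * exp(rnorm(1, 0, jit$rr_sd_sdlog))
  list(rhythm = r, rr = q)
}

draw_metadata <- function(n_mi, n_ctrl) {
  grp <- c(rep("MI", n_mi), rep("control", n_ctrl))
  age <- ifelse(grp == "MI", rnorm(n_mi + n_ctrl, 57.65, 9.03),
                rnorm(n_mi + n_ctrl, 57.71, 12.56))
  age <- pmin(pmax(round(age), 30), 90)
  male_p <- ifelse(grp == "MI", 29 / 34, 11 / 17)
  gender <- ifelse(rbinom(n_mi + n_ctrl, 1, male_p) == 1, "male", "female")
  bmi <- ifelse(grp == "MI", rnorm(n_mi + n_ctrl, 26.79, 4.11),
                rnorm(n_mi + n_ctrl, 23.09, 2.15))
  tibble::tibble(group = grp, age = age, gender = gender, bmi = round(bmi, 1))
}

draw_outcomes <- function(model, truth_z, group) {
  n <- nrow(truth_z)
  mi <- group == "MI"
  out <- list()
  for (nm in names(model$outcomes)) {
    o <- model$outcomes[[nm]]
    lin <- rep(o$intercept, n)
    for (ind in names(o$coef)) lin <- lin + o$coef[[ind]] * truth_z[[ind]]
    latent <- lin + rnorm(n, 0, o$noise_sd)
    val <- switch(o$type,
      continuous = latent,
      count = pmax(0, round(latent)),
      binary = {
        thr <- quantile(latent[mi], 1 - o$prevalence, names = FALSE, type = 7)
        as.numeric(latent > thr)
      })
    val[!mi] <- NA_real_
    out[[nm]] <- val
  }
  tibble::as_tibble(out)
}

#' Simulate a case-control cohort with known ground truth
#'
#' Draws `n_mi` patients and `n_ctrl` controls by jittering the two group
#' templates, simulates each subject's activity and RR recordings, and
#' generates prognosis outcomes (patients only) from the subjects'
#' ground-truth indicator values via `outcome_model`. The ground truth is
#' returned as a sidecar table and is never consumed by the analysis stages,
#' so parameter-recovery tests cannot leak.
#'
#' Outcome coefficients act on z-scored ground-truth indicators; the
#' supported indicator names are `day_mean`, `night_mean`, `m10`, `l5`,
#' `ra`, `midpoint_m10_h`, `midpoint_l5_h`, `mean_rr`, `sdrr`, `rmssd`,
#' `sd1`, `sd2`, `sd_ratio`.
#'
#' @param n_mi,n_ctrl Group sizes (>= 1).
#' @param mi,ctrl Group templates, lists with `rhythm` and `rr` elements
#'   (defaults [mi_template()] and [control_template()]).
#' @param outcomes An [outcome_model()]; default [default_outcome_model()].
#' @param jitter A [jitter_spec()].
#' @param seed Integer master seed.
#' @return A list of class `cohort_sim` with elements `subjects` (tibble with
#'   list-columns `activity` and `rr`), `cohort` (metadata + outcomes, one row
#'   per subject) and `truth` (ground-truth parameter and indicator sidecar).
#' @examples
#' sim <- simulate_cohort(n_mi = 3, n_ctrl = 2, seed = 1)
#' @export
simulate_cohort <- function(n_mi, n_ctrl, mi = mi_template(),
                            ctrl = control_template(),
                            outcomes = default_outcome_model(),
                            jitter = jitter_spec(), seed = 1) {
  stopifnot(n_mi >= 1, n_ctrl >= 1)
  if (!inherits(outcomes, "outcome_model")) outcomes <- outcome_model(outcomes)
  n <- n_mi + n_ctrl
  ids <- sprintf("S%03d", seq_len(n))

  meta <- withr::with_seed(derive_seed(seed, 0L), draw_metadata(n_mi, n_ctrl))
  meta <- dplyr::bind_cols(tibble::tibble(subject_id = ids), meta)

  subj_params <- purrr::map(seq_len(n), function(i) {
    template <- if (i <= n_mi) mi else ctrl
    withr::with_seed(derive_seed(seed, i), jitter_template(template, jitter))
  })
  activity <- purrr::map(seq_len(n), function(i) {
    simulate_activity(subj_params[[i]]$rhythm, seed = derive_seed(seed, 10000L + i))
  })
  rr <- purrr::map(seq_len(n), function(i) {
    simulate_rr(subj_params[[i]]$rr, seed = derive_seed(seed, 20000L + i))
  })

  truth_ind <- purrr::map_dfr(subj_params,
                              ~ truth_indicators(.x$rhythm, .x$rr))
  truth_par <- purrr::map_dfr(subj_params, function(p) {
    tibble::as_tibble(unclass(p$rhythm)[c("mesor", "amplitude", "acrophase_h",
                                          "fragmentation_p", "day_noise_sd",
                                          "night_noise_sd", "n_days")]) |>
      dplyr::bind_cols(tibble::as_tibble(unclass(p$rr)))
  })
  truth <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids, group = meta$group), truth_par, truth_ind)

  truth_z <- truth_ind
  for (nm in names(truth_z)) {
    s <- sd(truth_z[[nm]])
    truth_z[[nm]] <- if (is.na(s) || s == 0) truth_z[[nm]] * 0 else
      (truth_z[[nm]] - mean(truth_z[[nm]])) / s
  }
  out_tbl <- withr::with_seed(derive_seed(seed, 30000L),
                              draw_outcomes(outcomes, truth_z, meta$group))
  if (all(c("readmission_times", "readmission_days") %in% names(out_tbl))) {
    out_tbl$mean_readmission_days <- ifelse(
      !is.na(out_tbl$readmission_times) & out_tbl$readmission_times > 0,
      out_tbl$readmission_days / out_tbl$readmission_times, NA_real_)
  }

  structure(
    list(subjects = tibble::tibble(subject_id = ids, group = meta$group,
                                   activity = activity, rr = rr),
         cohort = dplyr::bind_cols(meta, out_tbl),
         truth = truth),
    class = "cohort_sim"
  )
}

#' Write a simulated cohort to disk
#'
#' Writes one activity CSV (`timestamp,counts,in_bed`) and one RR text file
#' (one interval in ms per line) per subject, the cohort metadata/outcome
#' CSV, the ground-truth sidecar CSV, and a JSON manifest listing all paths,
#' in the formats read back by [read_epochs()], [read_rr()] and
#' [analyze_cohort()].
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(file.path(dir, "activity"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::pmap(sim$subjects, function(subject_id, group, activity, rr) {
    act_path <- file.path("activity", paste0(subject_id, ".csv"))
    rr_path <- file.path("rr", paste0(subject_id, ".txt"))
    write_epochs(activity, file.path(dir, act_path))
    writeLines(format(rr$rr_ms, trim = TRUE, digits = 10),
               file.path(dir, rr_path))
    list(subject_id = subject_id, group = group,
         activity_file = act_path, rr_file = rr_path)
  })
  readr::write_csv(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$truth, file.path(dir, "ground_truth.csv"))
  manifest <- list(cohort_file = "cohort.csv",
                   ground_truth_file = "ground_truth.csv",
                   subjects = entries)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' Simulate an indicator-level null cohort table
#'
#' Draws a cohort table in which every indicator and outcome column is
#' independent of group membership and of each other (all from a shared
#' distribution). Intended for fast type-I-error calibration of the group
#' comparison and correlation machinery; raw recordings are not simulated.
#'
#' @param n_mi,n_ctrl Group sizes.
#' @param seed Integer seed.
#' @return A cohort tibble with metadata, indicator and outcome columns.
#' @export
simulate_null_cohort <- function(n_mi, n_ctrl, seed = 1) {
  n <- n_mi + n_ctrl
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = c(rep("MI", n_mi), rep("control", n_ctrl)),
      age = round(rnorm(n, 58, 10)),
      gender = ifelse(rbinom(n, 1, 0.7) == 1, "male", "female"),
      bmi = round(rnorm(n, 25, 3), 1),
      ra = rnorm(n, 0.8, 0.1),
      iv = rnorm(n, 1, 0.25),
      midpoint_m10_h = rnorm(n, 14, 1.5),
      rmssd = rnorm(n, 25, 8),
      admission_days = pmax(1, round(rnorm(n, 8, 3))),
      readmission_days = pmax(0, round(rnorm(n, 4, 3)))
    )
  })
}
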