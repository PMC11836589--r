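#' Rest-activity rhythm parameters for the activity simulator
#'
#' Describes one subject's (or one group template's) rest-activity rhythm as a
#' clipped 24-h cosine plus period-specific noise and fragmentation. Expected
#' activity at clock time \eqn{t} (hours) is
#' \deqn{\max(0,\; m + A\cos(2\pi (t - \phi)/24) + \epsilon_t)}
#' with mesor \eqn{m}, amplitude \eqn{A} and acrophase \eqn{\phi}; the noise
#' SD is `night_noise_sd` inside the bed window and `day_noise_sd` outside.
#' With probability `fragmentation_p` an epoch's value is instead drawn from
#' the opposite period's distribution (the antiphase clock time with the
#' opposite noise SD), which fragments the rhythm without changing its phase.
#'
#' @param mesor Rhythm-adjusted mean activity, counts/min (>= 0).
#' @param amplitude Cosine amplitude, counts/min (>= 0). May exceed `mesor`;
#'   activity is clipped at zero.
#' @param acrophase_h Clock hour of peak activity, in `[0, 24)`.
#' @param fragmentation_p Per-epoch probability in `[0, 1]` of swapping in a
#'   draw from the opposite (day/night) period.
#' @param day_noise_sd,night_noise_sd Noise SDs (counts/min, >= 0) outside and
#'   inside the bed window.
#' @param bed_start_h,bed_end_h Bed window `[bed_start_h, bed_end_h)` in clock
#'   hours; may wrap midnight; must have positive length.
#' @param n_days Number of simulated days (integer >= 1).
#' @param epoch_s Epoch length in seconds (default 60; must divide 3600).
#'
#' @return A list of class `rhythm_params`.
#' @seealso [simulate_activity()], [mi_template()], [control_template()]
#' @export
rhythm_params <- function(mesor = 100, amplitude = 90, acrophase_h = 14,
                          fragmentation_p = 0.05, day_noise_sd = 50,
                          night_noise_sd = 15, bed_start_h = 23,
                          bed_end_h = 7, n_days = 5, epoch_s = 60) {
  stopifnot(mesor >= 0, amplitude >= 0, day_noise_sd >= 0, night_noise_sd >= 0)
  if (fragmentation_p < 0 || fragmentation_p > 1) {
    abort("`fragmentation_p` must be a probability in [0, 1].")
  }
  if (n_days < 1) abort("`n_days` must be a positive integer.")
  if (3600 %% epoch_s != 0) abort("`epoch_s` must divide 3600.")
  if ((bed_start_h %% 24) == (bed_end_h %% 24)) {
    abort("bed interval has zero length")
  }
  structure(
    list(mesor = mesor, amplitude = amplitude,
         acrophase_h = acrophase_h %% 24,
         fragmentation_p = fragmentation_p,
         day_noise_sd = day_noise_sd, night_noise_sd = night_noise_sd,
         bed_start_h = bed_start_h %% 24, bed_end_h = bed_end_h %% 24,
         n_days = as.integer(n_days), epoch_s = as.integer(epoch_s)),
    class = "rhythm_params"
  )
}

#' RR-interval simulation parameters
#'
#' Simulated RR intervals are `mean_rr_ms` plus a white component with SD
#' `short_term_sd_ms` (so successive differences have SD
#' `short_term_sd_ms * sqrt(2)`) plus a slowly drifting AR(1) component with
#' stationary SD `long_term_sd_ms`. Keeping
#' `mean_rr_ms - 4 * (short_term_sd_ms + long_term_sd_ms) > 0` is recommended
#' so that the positivity clip is essentially never active.
#'
#' @param mean_rr_ms Mean RR interval in ms (> 0).
#' @param short_term_sd_ms White (beat-to-beat) SD in ms (>= 0).
#' @param long_term_sd_ms Slow-drift SD in ms (>= 0).
#' @param duration_min Recording duration in minutes (> 0).
#'
#' @return A list of class `rr_sim_params`.
#' @seealso [simulate_rr()]
#' @export
rr_sim_params <- function(mean_rr_ms = 850, short_term_sd_ms = 20,
                          long_term_sd_ms = 40, duration_min = 15) {
  stopifnot(mean_rr_ms > 0, short_term_sd_ms >= 0, long_term_sd_ms >= 0)
  if (duration_min <= 0) abort("`duration_min` must be positive.")
  structure(
    list(mean_rr_ms = mean_rr_ms, short_term_sd_ms = short_term_sd_ms,
         long_term_sd_ms = long_term_sd_ms, duration_min = duration_min),
    class = "rr_sim_params"
  )
}

# Indicator names for which a ground-truth (noise-free) value can be derived
# from the simulation parameters; outcome models may only reference these.
truth_indicator_names <- function() {
  c("day_mean", "night_mean", "m10", "l5", "ra",
    "midpoint_m10_h", "midpoint_l5_h",
    "mean_rr", "sdrr", "rmssd", "sd1", "sd2", "sd_ratio")
}

#' Outcome model linking latent rhythm/HRV indicators to prognosis outcomes
#'
#' Each outcome is generated from the ground-truth (noise-free) indicator
#' values of each simulated subject: a linear predictor over z-scored
#' indicators plus Gaussian noise. Continuous outcomes use the identity link
#' (optionally floored at zero and rounded); binary outcomes threshold the
#' latent Gaussian at the quantile giving the requested prevalence, which
#' keeps point-biserial correlations with the indicators analyzable.
#'
#' @param outcomes A named list; each element is a list with fields
#'   `coef` (named numeric vector over indicator names, see
#'   [simulate_cohort()] for the supported set), `noise_sd` (>= 0),
#'   `type` (`"continuous"`, `"count"` or `"binary"`),
#'   `intercept` (continuous/count only, default 0) and
#'   `prevalence` (binary only, in (0,1)).
#'
#' @return A list of class `outcome_model`.
#' @export
outcome_model <- function(outcomes) {
  if (!is.list(outcomes) || is.null(names(outcomes)) || any(names(outcomes) == "")) {
    abort("`outcomes` must be a named list of outcome definitions.")
  }
  known <- truth_indicator_names()
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    o$type <- match.arg(o$type %||% "continuous", c("continuous", "count", "binary"))
    o$noise_sd <- o$noise_sd %||% 1
    if (o$noise_sd < 0) abort("`noise_sd` must be >= 0.")
    o$intercept <- o$intercept %||% 0
    o$prevalence <- o$prevalence %||% 0.5
    bad <- setdiff(names(o$coef), known)
    if (length(bad) > 0L) {
      abort(sprintf("outcome '%s' references unknown indicator(s): %s",
                    nm, paste(bad, collapse = ", ")))
    }
    outcomes[[nm]] <- o
  }
  structure(list(outcomes = outcomes), class = "outcome_model")
}

#' Default prognosis outcome model
#'
#' Encodes the qualitative prognosis structure studied in acute-MI cohorts:
#' a delayed activity peak (later M10 midpoint) predicts more and longer
#' readmissions, higher nighttime activity predicts a longer index admission,
#' and a higher Poincare SD ratio predicts repeat catheterization.
#'
#' @param effect Common effect size (per 1 SD of indicator) scaling all
#'   nonzero coefficients; default 2.
#' @param noise_sd Outcome noise SD; default 3.
#' @return An [outcome_model()].
#' @export
default_outcome_model <- function(effect = 2, noise_sd = 3) {
  outcome_model(list(
    admission_days = list(coef = c(night_mean = effect), intercept = 8,
                          noise_sd = noise_sd, type = "count"),
    any_readmission = list(coef = c(midpoint_m10_h = effect), type = "binary",
                           noise_sd = noise_sd, prevalence = 0.4),
    any_icu_readmission = list(coef = c(midpoint_m10_h = effect), type = "binary",
                               noise_sd = noise_sd, prevalence = 0.2),
    readmission_times = list(coef = c(midpoint_m10_h = effect / 2), intercept = 1,
                             noise_sd = noise_sd / 3, type = "count"),
    readmission_days = list(coef = c(midpoint_m10_h = effect), intercept = 4,
                            noise_sd = noise_sd, type = "count"),
    any_catheterization = list(coef = c(sd_ratio = effect), type = "binary",
                               noise_sd = noise_sd, prevalence = 0.3)
  ))
}

#' Group templates for a synthetic case-control cohort
#'
#' `mi_template()` encodes the rest-activity and HRV phenotype of an acute-MI
#' ICU patient relative to `control_template()`: lower daytime activity and
#' cosine amplitude, a delayed acrophase, more fragmentation, a 24-h HRV
#' recording with reduced short-term RR variability, and a monitoring span of
#' about 6 days versus 14 days of ambulatory wear in controls.
#'
#' @return A list with elements `rhythm` ([rhythm_params()]) and
#'   `rr` ([rr_sim_params()]).
#' @export
mi_template <- function() {
  list(
    rhythm = rhythm_params(mesor = 45, amplitude = 80, acrophase_h = 15.5,
                           fragmentation_p = 0.15, day_noise_sd = 40,
                           night_noise_sd = 20, bed_start_h = 22.5,
                           bed_end_h = 7, n_days = 6),
    rr = rr_sim_params(mean_rr_ms = 850, short_term_sd_ms = 13,
                       long_term_sd_ms = 30, duration_min = 1440)
  )
}

#' @rdname mi_template
#' @export
control_template <- function() {
  list(
    rhythm = rhythm_params(mesor = 80, amplitude = 160, acrophase_h = 13.5,
                           fragmentation_p = 0.05, day_noise_sd = 60,
                           night_noise_sd = 15, bed_start_h = 22,
                           bed_end_h = 6, n_days = 14),
    rr = rr_sim_params(mean_rr_ms = 850, short_term_sd_ms = 22,
                       long_term_sd_ms = 40, duration_min = 15)
  )
}

#' Between-subject jitter applied around a group template
#'
#' Mesor, amplitude and the noise/RR variability scales are jittered
#' multiplicatively (log-normal), the acrophase additively (wrapped normal),
#' fragmentation on the logit scale, and the monitoring span in whole days.
#'
#' @param mesor_sdlog,amplitude_sdlog,noise_sdlog,rr_sd_sdlog Log-normal SDs.
#' @param acrophase_sd_h Wrapped-normal SD of the acrophase, hours.
#' @param frag_sdlogit Logit-normal SD of the fragmentation probability.
#' @param rr_mean_sd SD of the subject mean RR, ms.
#' @param n_days_sd SD of the per-subject monitoring span, days (rounded,
#'   clipped to >= 1).
#' @return A list of class `jitter_spec`.
#' @export
jitter_spec <- function(mesor_sdlog = 0.2, amplitude_sdlog = 0.2,
                        acrophase_sd_h = 0.75, frag_sdlogit = 0.3,
                        noise_sdlog = 0.15, rr_mean_sd = 60,
                        rr_sd_sdlog = 0.15, n_days_sd = 2) {
  structure(as.list(environment()), class = "jitter_spec")
}
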