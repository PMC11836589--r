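# Scaled-down group templates: the same phenotype contrasts as the package
# defaults, on 4-day recordings and short RR traces, for fast tests.
small_mi_template <- function() {
  t <- mi_template()
  t$rhythm$n_days <- 4L
  t$rr$duration_min <- 10
  t
}

small_ctrl_template <- function() {
  t <- control_template()
  t$rhythm$n_days <- 4L
  t$rr$duration_min <- 10
  t
}

small_cohort <- function(n_mi, n_ctrl, seed, ...) {
  simulate_cohort(n_mi = n_mi, n_ctrl = n_ctrl,
                  mi = small_mi_template(), ctrl = small_ctrl_template(),
                  jitter = jitter_spec(n_days_sd = 0), seed = seed, ...)
}
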