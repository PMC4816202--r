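# Shared builders for tests: flat (covariate-free) hazard and cost
# structures, and small cohort configurations.

no_loghr <- stats::setNames(numeric(0), character(0))

# Transition params with constant per-cycle rates and no covariates.
# Zero rates are encoded as log_base = -Inf (hazard exactly 0).
tp_flat <- function(ami = 0, is = 0, hs = 0, cvdd = 0, ncvdd = 0,
                    post_cvd = 0.04, post_ncvd = 0.012) {
  fe <- function(r) list(log_base = if (r > 0) log(r) else -Inf, loghr = no_loghr)
  pe <- list(cvd_death = fe(post_cvd), noncvd_death = fe(post_ncvd))
  transition_params(
    first_event = list(
      ami = fe(ami), ischaemic_stroke = fe(is), haemorrhagic_stroke = fe(hs),
      cvd_death = fe(cvdd), noncvd_death = fe(ncvdd)
    ),
    post_event = list(ami = pe, ischaemic_stroke = pe, haemorrhagic_stroke = pe)
  )
}

# Covariate-free nested cost triplet compatible with the default shared
# component means (primary care 90, diagnostics 30, CVD drugs 20, non-CVD
# drugs 60 per cycle).
flat_cost_params <- function(trend = c(total = 10, cvd = 8, chd = 7),
                             with_events = FALSE,
                             death_increments = FALSE) {
  bands <- function(b1, lr) list(bands = c(b1, b1 * 0.3, b1 * 0.2, b1 * 0.14),
                                 long_run = lr)
  ev <- function(scale) {
    if (!with_events) return(list())
    list(ami = bands(5028 * scale, 521 * scale),
         ischaemic_stroke = bands(5500 * scale, 300 * scale),
         haemorrhagic_stroke = bands(6800 * scale, 350 * scale))
  }
  di <- function(cvd, noncvd) {
    if (!death_increments) return(c(cvd_death = 0, noncvd_death = 0))
    c(cvd_death = cvd, noncvd_death = noncvd)
  }
  list(
    total = panel_cost_params("total", baseline = 341, trend = trend[["total"]],
                              event_increments = ev(1),
                              death_increments = di(2008, 2240)),
    cvd = panel_cost_params("cvd", baseline = 270, trend = trend[["cvd"]],
                            event_increments = ev(0.9),
                            death_increments = di(1500, 500)),
    chd = panel_cost_params("chd", baseline = 240, trend = trend[["chd"]],
                            event_increments = ev(0.8),
                            death_increments = di(1200, 300))
  )
}

# Hazard-params list (sim_config shape) with constant rates, no covariates.
hp_flat <- function(...) unclass(tp_flat(...))

# A small quiet configuration for pipeline tests.
quick_config <- function(n = 500, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# Hand-built single-profile baseline rows for window tests.
mini_baseline <- function(n) {
  tibble::tibble(
    patient_id = seq_len(n),
    diagnosis_date = as.Date("2004-01-01"),
    entry_date = as.Date("2004-01-01"),
    sex = rep(c("male", "female"), length.out = n),
    age_at_entry = 60 + seq_len(n),
    diagnosis = "stable_angina",
    heart_failure = 0L, renal_disease = 0L, diabetes = 0L,
    copd = 0L, cancer = 0L, smoking = 0L,
    heart_rate = 75, creatinine = 85
  )
}
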