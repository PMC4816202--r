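#' Event and diagnosis vocabularies
#'
#' Canonical level sets used throughout the package: the five first events
#' competing from the stable state, the three non-fatal event types that open
#' a post-event phase, and the five qualifying diagnosis categories.
#'
#' @name vocab
#' @keywords internal
NULL

NONFATAL_EVENTS <- c("ami", "ischaemic_stroke", "haemorrhagic_stroke")
DEATH_EVENTS <- c("cvd_death", "noncvd_death")
FIRST_EVENTS <- c(NONFATAL_EVENTS, DEATH_EVENTS)
DIAGNOSES <- c("stable_angina", "unstable_angina", "stemi", "nstemi", "other_chd")
COST_CATEGORIES <- c("total", "cvd", "chd")

#' 90-day panel cost parameters
#'
#' Container for the additive 90-day cost structure of one cost category:
#' a baseline per-cycle cost, a linear per-cycle trend, additive per-cycle
#' covariate effects, event increments in four 90-day bands after each
#' non-fatal event followed by a constant long-run increment, and a one-off
#' increment in the cycle of death.
#'
#' @param category One of `"total"`, `"cvd"`, `"chd"`.
#' @param baseline Baseline cost (GBP per 90-day cycle) for the reference
#'   covariate profile in cycle 1.
#' @param trend Additive cost change (GBP per cycle) per elapsed cycle.
#' @param covariate_effects Named numeric vector of additive GBP-per-cycle
#'   effects on the design-covariate scale (see [design_covariates()]).
#' @param event_increments Named list, one element per non-fatal event type
#'   (`ami`, `ischaemic_stroke`, `haemorrhagic_stroke`), each a list with
#'   `bands` (numeric length 4, GBP increments for the event cycle and the
#'   following three cycles) and `long_run` (GBP per cycle from the fifth
#'   post-event cycle onward).
#' @param death_increments Named numeric vector with elements `cvd_death`
#'   and `noncvd_death`: GBP increments in the cycle of death.
#'
#' @return An object of class `panel_cost_params`.
#' @export
#' @examples
#' panel_cost_params(
#'   baseline = 341, trend = 10,
#'   event_increments = list(
#'     ami = list(bands = c(5028, 1500, 1000, 700), long_run = 521)
#'   ),
#'   death_increments = c(cvd_death = 2008, noncvd_death = 2240)
#' )
panel_cost_params <- function(category = "total",
                              baseline,
                              trend = 0,
                              covariate_effects = numeric(),
                              event_increments = list(),
                              death_increments = c(cvd_death = 0, noncvd_death = 0)) {
  category <- match.arg(category, COST_CATEGORIES)
  if (!is.numeric(baseline) || length(baseline) != 1 || !is.finite(baseline)) {
    stop_config("`baseline` must be a single finite number", field = "baseline")
  }
  if (!is.numeric(trend) || length(trend) != 1 || !is.finite(trend)) {
    stop_config("`trend` must be a single finite number", field = "trend")
  }
  bad <- setdiff(names(event_increments), NONFATAL_EVENTS)
  if (length(bad)) {
    stop_config(paste0("unknown event type in `event_increments`: ", paste(bad, collapse = ", ")),
                field = "event_increments")
  }
  event_increments <- lapply(event_increments, function(e) {
    if (is.null(e$bands) || length(e$bands) != 4 || !all(is.finite(e$bands))) {
      stop_config("each event increment needs 4 finite band values", field = "event_increments")
    }
    if (is.null(e$long_run) || !is.finite(e$long_run)) {
      stop_config("each event increment needs a finite `long_run` value", field = "event_increments")
    }
    list(bands = as.numeric(e$bands), long_run = as.numeric(e$long_run))
  })
  di <- c(cvd_death = 0, noncvd_death = 0)
  di[names(death_increments)] <- death_increments
  structure(
    list(
      category = category,
      baseline = as.numeric(baseline),
      trend = as.numeric(trend),
      covariate_effects = covariate_effects,
      event_increments = event_increments,
      death_increments = di
    ),
    class = "panel_cost_params"
  )
}

#' @export
print.panel_cost_params <- function(x, ...) {
  cat(sprintf(
    "<panel_cost_params: %s>\n  baseline %.2f GBP/cycle, trend %+.2f GBP/cycle\n",
    x$category, x$baseline, x$trend
  ))
  if (length(x$covariate_effects)) {
    cat("  covariate effects:",
        paste(sprintf("%s %+0.1f", names(x$covariate_effects), x$covariate_effects),
              collapse = ", "), "\n")
  }
  for (ev in names(x$event_increments)) {
    e <- x$event_increments[[ev]]
    cat(sprintf("  %s: bands %s, long-run %+0.1f\n", ev,
                paste(sprintf("%+0.1f", e$bands), collapse = " "), e$long_run))
  }
  cat(sprintf("  death-cycle increments: CVD %+0.1f, non-CVD %+0.1f\n",
              x$death_increments[["cvd_death"]], x$death_increments[["noncvd_death"]]))
  invisible(x)
}

#' Default ground-truth cost parameters
#'
#' The default per-cycle cost structure used by the synthetic cohort
#' generator, one [panel_cost_params()] per cost category (total, CVD, CHD).
#' The total-category values anchor on published 90-day estimates for a UK
#' SCAD population: GBP 341 baseline with a GBP 10 per-cycle trend, a
#' GBP 5028 increment in the 90 days containing a non-fatal AMI followed by
#' a GBP 521 long-run increment, and death-cycle increments of GBP 2008
#' (CVD death) and GBP 2240 (non-CVD death). The CVD and CHD categories are
#' nested within the total with monotone effects so that simulated category
#' costs always satisfy chd <= cvd <= total.
#'
#' @return Named list of three `panel_cost_params` objects (`total`, `cvd`,
#'   `chd`).
#' @export
default_cost_params <- function() {
  eff <- function(female, age, hf, renal, diab, smok, nstemi, stemi, ua, ochd) {
    c(sex_female = female, age10c = age, heart_failure = hf, renal_disease = renal,
      diabetes = diab, smoking = smok, diag_nstemi = nstemi, diag_stemi = stemi,
      diag_unstable_angina = ua, diag_other_chd = ochd)
  }
  list(
    total = panel_cost_params(
      "total", baseline = 341, trend = 10,
      covariate_effects = eff(-30, 30, 200, 400, 80, 40, 164, 150, 120, 30),
      event_increments = list(
        ami = list(bands = c(5028, 1400, 800, 449), long_run = 521),
        ischaemic_stroke = list(bands = c(5500, 1600, 1000, 802), long_run = 300),
        haemorrhagic_stroke = list(bands = c(6800, 1900, 1100, 677), long_run = 350)
      ),
      death_increments = c(cvd_death = 2008, noncvd_death = 2240)
    ),
    cvd = panel_cost_params(
      "cvd", baseline = 270, trend = 8,
      covariate_effects = eff(-30, 30, 150, 80, 50, 30, 120, 110, 90, 20),
      event_increments = list(
        ami = list(bands = c(4800, 1300, 750, 420), long_run = 480),
        ischaemic_stroke = list(bands = c(5300, 1500, 950, 750), long_run = 280),
        haemorrhagic_stroke = list(bands = c(6500, 1800, 1050, 640), long_run = 330)
      ),
      death_increments = c(cvd_death = 1500, noncvd_death = 500)
    ),
    chd = panel_cost_params(
      "chd", baseline = 240, trend = 7,
      covariate_effects = eff(-30, 30, 120, 60, 40, 25, 100, 90, 70, 15),
      event_increments = list(
        ami = list(bands = c(4600, 1250, 700, 400), long_run = 450),
        ischaemic_stroke = list(bands = c(0, 0, 0, 0), long_run = 0),
        haemorrhagic_stroke = list(bands = c(0, 0, 0, 0), long_run = 0)
      ),
      death_increments = c(cvd_death = 1200, noncvd_death = 300)
    )
  )
}

#' Default transition hazard parameters
#'
#' Ground-truth cause-specific hazards (events per 90-day cycle at the
#' reference profile: male, age 67) with proportional log-hazard ratios for
#' centred age (per decade, `age10c`) and female sex. First events compete
#' from the stable state; after a non-fatal event only the two death
#' transitions remain.
#'
#' @return A list with elements `first_event` (one element per first event
#'   type, each `list(log_base, loghr)`) and `post_event` (one element per
#'   non-fatal event type, each with `cvd_death` and `noncvd_death`
#'   sub-elements).
#' @export
default_hazard_params <- function() {
  fe <- function(rate, age, female) {
    list(log_base = log(rate), loghr = c(age10c = age, sex_female = female))
  }
  # Calibrated so that across the cohort's age span (about 52 to 84 years
  # at the decile means) the modelled five-year risk of a first
  # cardiovascular event runs from a few percent to above forty percent,
  # with non-CVD death the dominant competing risk at younger ages --
  # the gradient structure reported for UK SCAD populations.
  list(
    first_event = list(
      ami = fe(0.0045, 0.95, -0.20),
      ischaemic_stroke = fe(0.0018, 0.95, 0),
      haemorrhagic_stroke = fe(0.00045, 0.95, 0),
      cvd_death = fe(0.00225, 0.95, -0.10),
      noncvd_death = fe(0.011, 0.55, -0.05)
    ),
    post_event = list(
      ami = list(cvd_death = fe(0.035, 0.55, 0), noncvd_death = fe(0.012, 0.55, 0)),
      ischaemic_stroke = list(cvd_death = fe(0.045, 0.55, 0), noncvd_death = fe(0.012, 0.55, 0)),
      haemorrhagic_stroke = list(cvd_death = fe(0.065, 0.55, 0), noncvd_death = fe(0.012, 0.55, 0))
    )
  )
}

#' Simulation configuration for the synthetic SCAD cohort
#'
#' Bundles every parameter of the synthetic-data generator: cohort
#' composition (sex mix, age distributions, diagnosis mix, comorbidity
#' prevalences, biomarker distributions and missingness), the competing-risk
#' event process on the 90-day cycle grid, the ground-truth period cost
#' structure, cost noise, censoring and follow-up horizon.
#'
#' Defaults emulate a UK stable coronary artery disease cohort: 44% female;
#' mean age 67 (men) and 72 (women); diagnosis mix 47.4% stable angina,
#' 13.5% unstable angina, 6.7% STEMI, 9.7% NSTEMI, 22.6% other CHD
#' (renormalized to sum to one).
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; all generator output is deterministic given the
#'   seed and configuration.
#' @param female_fraction Probability a patient is female.
#' @param age_mean_male,age_mean_female,age_sd Age-at-entry distribution
#'   (years, normal, truncated to `age_range`).
#' @param age_range Truncation bounds for age at entry (years).
#' @param diagnosis_mix Named probabilities over the five diagnosis
#'   categories; must sum to 1 within 1e-9.
#' @param comorbidity_prevalences Named probabilities for each binary flag,
#'   evaluated at the reference age (67).
#' @param comorbidity_age_logor Named log-odds ratios per decade of age for
#'   the comorbidity flags (prevalence follows a logistic-in-age curve, as
#'   comorbidity burden rises with age in SCAD cohorts).
#' @param biomarker_means,biomarker_sds Named normal parameters for each
#'   continuous biomarker.
#' @param missingness_rates Named per-biomarker probability of a missing
#'   value (missing completely at random).
#' @param hazard_params Transition hazards; see [default_hazard_params()].
#' @param cost_params Ground-truth cost structure: a named list of three
#'   [panel_cost_params()] (`total`, `cvd`, `chd`); see
#'   [default_cost_params()].
#' @param cost_components Named per-cycle mean costs (GBP) of the shared
#'   non-inpatient components: `primary_care`, `diagnostics`, `drugs_cvd`,
#'   `drugs_noncvd`.
#' @param gamma_shape Shape of the gamma noise on each cost component
#'   (scale = mean / shape); `Inf` gives noise-free costs equal to their
#'   means.
#' @param censoring_rate Per-cycle probability of non-death censoring,
#'   independent of events and costs.
#' @param horizon_cycles Administrative follow-up horizon in 90-day cycles.
#'
#' @return An object of class `scad_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 42)
#' cohort <- generate_baseline(cfg)
sim_config <- function(n_patients = 1000,
                       seed = 1L,
                       female_fraction = 0.44,
                       age_mean_male = 67,
                       age_mean_female = 72,
                       age_sd = 12,
                       age_range = c(45, 92),
                       diagnosis_mix = c(stable_angina = 0.474, unstable_angina = 0.135,
                                         stemi = 0.067, nstemi = 0.097, other_chd = 0.226),
                       comorbidity_prevalences = c(heart_failure = 0.08, renal_disease = 0.05,
                                                   diabetes = 0.15, copd = 0.10, cancer = 0.08,
                                                   smoking = 0.18),
                       comorbidity_age_logor = c(heart_failure = 0.7, renal_disease = 0.7,
                                                 diabetes = 0.25, copd = 0.4, cancer = 0.45,
                                                 smoking = -0.35),
                       biomarker_means = c(heart_rate = 75, creatinine = 85),
                       biomarker_sds = c(heart_rate = 12, creatinine = 20),
                       missingness_rates = c(heart_rate = 0.25, creatinine = 0.30),
                       hazard_params = default_hazard_params(),
                       cost_params = default_cost_params(),
                       cost_components = c(primary_care = 90, diagnostics = 30,
                                           drugs_cvd = 20, drugs_noncvd = 60),
                       gamma_shape = 0.5,
                       censoring_rate = 0.005,
                       horizon_cycles = 40L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1 ||
      n_patients != floor(n_patients)) {
    stop_config("`n_patients` must be a positive integer", field = "n_patients")
  }
  check_prob(female_fraction, "female_fraction")
  check_prob(censoring_rate, "censoring_rate")
  if (!setequal(names(diagnosis_mix), DIAGNOSES)) {
    stop_config("`diagnosis_mix` must name the five diagnosis categories",
                field = "diagnosis_mix")
  }
  check_prob(diagnosis_mix, "diagnosis_mix")
  # Renormalize percentage-derived mixes off by rounding; reject real errors.
  s <- sum(diagnosis_mix)
  if (abs(s - 1) > 0.005) {
    stop_config(sprintf("`diagnosis_mix` sums to %.4f, not 1", s), field = "diagnosis_mix")
  }
  diagnosis_mix <- diagnosis_mix / s
  check_prob(comorbidity_prevalences, "comorbidity_prevalences")
  extra <- setdiff(names(comorbidity_age_logor), names(comorbidity_prevalences))
  if (length(extra)) {
    stop_config(paste0("`comorbidity_age_logor` names unknown flag: ",
                       paste(extra, collapse = ", ")), field = "comorbidity_age_logor")
  }
  if (!setequal(names(biomarker_means), names(biomarker_sds))) {
    stop_config("`biomarker_means` and `biomarker_sds` must name the same biomarkers",
                field = "biomarker_sds")
  }
  if (length(missingness_rates)) {
    check_prob(missingness_rates, "missingness_rates")
    bad <- setdiff(names(missingness_rates), names(biomarker_means))
    if (length(bad)) {
      stop_config(paste0("`missingness_rates` names unknown biomarker: ",
                         paste(bad, collapse = ", ")), field = "missingness_rates")
    }
  }
  if (!is.numeric(gamma_shape) || length(gamma_shape) != 1 || is.na(gamma_shape) ||
      gamma_shape <= 0) {
    stop_config("`gamma_shape` must be a positive number", field = "gamma_shape")
  }
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1) {
    stop_config("`horizon_cycles` must be a positive integer", field = "horizon_cycles")
  }
  validate_hazard_params(hazard_params)
  if (!setequal(names(cost_params), COST_CATEGORIES)) {
    stop_config("`cost_params` must be a named list with elements total, cvd, chd",
                field = "cost_params")
  }
  for (cp in cost_params) {
    if (!inherits(cp, "panel_cost_params")) {
      stop_config("each element of `cost_params` must be a panel_cost_params object",
                  field = "cost_params")
    }
  }
  need <- c("primary_care", "diagnostics", "drugs_cvd", "drugs_noncvd")
  if (!all(need %in% names(cost_components)) || any(cost_components < 0)) {
    stop_config("`cost_components` must supply nonnegative means for primary_care, diagnostics, drugs_cvd, drugs_noncvd",
                field = "cost_components")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      female_fraction = female_fraction,
      age_mean_male = age_mean_male, age_mean_female = age_mean_female,
      age_sd = age_sd, age_range = age_range,
      diagnosis_mix = diagnosis_mix,
      comorbidity_prevalences = comorbidity_prevalences,
      comorbidity_age_logor = comorbidity_age_logor,
      biomarker_means = biomarker_means, biomarker_sds = biomarker_sds,
      missingness_rates = missingness_rates,
      hazard_params = hazard_params, cost_params = cost_params,
      cost_components = cost_components[need],
      gamma_shape = gamma_shape, censoring_rate = censoring_rate,
      horizon_cycles = as.integer(horizon_cycles)
    ),
    class = "scad_sim_config"
  )
}

validate_hazard_params <- function(hp) {
  if (!all(c("first_event", "post_event") %in% names(hp))) {
    stop_config("`hazard_params` must have elements `first_event` and `post_event`",
                field = "hazard_params")
  }
  missing_fe <- setdiff(FIRST_EVENTS, names(hp$first_event))
  if (length(missing_fe)) {
    stop_config(paste0("`hazard_params$first_event` missing transition: ",
                       paste(missing_fe, collapse = ", ")), field = "hazard_params")
  }
  missing_pe <- setdiff(NONFATAL_EVENTS, names(hp$post_event))
  if (length(missing_pe)) {
    stop_config(paste0("`hazard_params$post_event` missing event type: ",
                       paste(missing_pe, collapse = ", ")), field = "hazard_params")
  }
  check_tr <- function(tr, label) {
    if (is.null(tr$log_base) || !is.finite(tr$log_base) && !identical(tr$log_base, -Inf)) {
      stop_config(paste0("transition `", label, "` needs a finite log_base"),
                  field = "hazard_params")
    }
  }
  for (ev in FIRST_EVENTS) check_tr(hp$first_event[[ev]], ev)
  for (ev in NONFATAL_EVENTS) {
    for (d in DEATH_EVENTS) check_tr(hp$post_event[[ev]][[d]], paste(ev, d, sep = "->"))
  }
  invisible(hp)
}

#' @export
print.scad_sim_config <- function(x, ...) {
  cat(sprintf("<scad_sim_config: %d patients, seed %d, horizon %d cycles>\n",
              x$n_patients, x$seed, x$horizon_cycles))
  cat(sprintf("  female fraction %.3f; ages N(%g/%g, %g) on [%g, %g]\n",
              x$female_fraction, x$age_mean_male, x$age_mean_female, x$age_sd,
              x$age_range[1], x$age_range[2]))
  cat("  diagnosis mix:",
      paste(sprintf("%s %.3f", names(x$diagnosis_mix), x$diagnosis_mix), collapse = ", "), "\n")
  cat(sprintf("  gamma shape %g; censoring %.4f/cycle\n", x$gamma_shape, x$censoring_rate))
  invisible(x)
}
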