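# Synthetic SCAD cohort generator: baseline covariates, competing-risk
# events on the 90-day cycle grid, and gamma-noise period costs with
# additive event increments. Stands in for a linked-EHR extract so the
# whole downstream pipeline is testable without any data access.

#' Generate a synthetic baseline table
#'
#' Draws one row per patient: sex, age at entry (truncated normal), SCAD
#' diagnosis category, binary comorbidity flags, smoking status, and
#' continuous biomarkers with missing-completely-at-random gaps at the
#' configured rates. The entry date applies the cohort rule: date of
#' diagnosis for stable angina / other CHD, 182 days after diagnosis for an
#' acute coronary syndrome (unstable angina, STEMI, NSTEMI).
#'
#' @param config A [sim_config()] object.
#' @return A tibble with `n_patients` rows: `patient_id`, `diagnosis_date`,
#'   `entry_date`, `sex`, `age_at_entry`, `diagnosis`, one column per
#'   comorbidity flag (0/1), and one column per biomarker (NA where
#'   missing). Deterministic given `config$seed`.
#' @export
#' @examples
#' cohort <- generate_baseline(sim_config(n_patients = 100, seed = 7))
#' table(cohort$diagnosis)
generate_baseline <- function(config) {
  stopifnot(inherits(config, "scad_sim_config"))
  n <- config$n_patients
  set.seed(config$seed)

  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  mu <- ifelse(sex == "female", config$age_mean_female, config$age_mean_male)
  lo <- config$age_range[1]; hi <- config$age_range[2]
  plo <- pnorm(lo, mu, config$age_sd); phi <- pnorm(hi, mu, config$age_sd)
  age <- qnorm(plo + runif(n) * (phi - plo), mu, config$age_sd)

  diagnosis <- sample(names(config$diagnosis_mix), n, replace = TRUE,
                      prob = config$diagnosis_mix)

  diagnosis_date <- as.Date("2001-01-01") +
    floor(runif(n) * as.numeric(as.Date("2008-12-31") - as.Date("2001-01-01")))

  out <- tibble::tibble(
    patient_id = seq_len(n),
    diagnosis_date = diagnosis_date,
    entry_date = derive_entry_date(diagnosis_date, diagnosis),
    sex = sex,
    age_at_entry = age,
    diagnosis = diagnosis
  )
  age10c <- (age - 67) / 10
  for (flag in names(config$comorbidity_prevalences)) {
    lo <- config$comorbidity_age_logor[flag]
    logit <- qlogis(config$comorbidity_prevalences[[flag]]) +
      ifelse(is.na(lo), 0, lo) * age10c
    out[[flag]] <- as.integer(runif(n) < plogis(logit))
  }
  for (bm in names(config$biomarker_means)) {
    v <- rnorm(n, config$biomarker_means[[bm]], config$biomarker_sds[[bm]])
    rate <- config$missingness_rates[bm]
    if (!is.na(rate) && rate > 0) v[runif(n) < rate] <- NA_real_
    out[[bm]] <- v
  }
  out
}

#' Numeric design covariates for hazard and cost models
#'
#' Expands a baseline table into the numeric covariate columns that hazard
#' log-hazard-ratios and additive cost effects are named against: centred
#' age per decade (`age10c`, centred at 67), `sex_female`, the comorbidity
#' flags, and treatment-difference dummies for diagnosis relative to the
#' stable-angina reference (`diag_unstable_angina`, `diag_stemi`,
#' `diag_nstemi`, `diag_other_chd`). Biomarker columns are passed through
#' unchanged.
#'
#' @param baseline A baseline tibble (see [generate_baseline()]).
#' @param age_center Age (years) treated as the covariate reference.
#' @return A tibble of numeric covariates aligned with `baseline` rows.
#' @export
design_covariates <- function(baseline, age_center = 67) {
  fixed <- c("patient_id", "diagnosis_date", "entry_date", "exit_date",
             "exit_reason", "sex", "age_at_entry", "diagnosis")
  out <- tibble::tibble(
    age10c = (baseline$age_at_entry - age_center) / 10,
    sex_female = as.numeric(baseline$sex == "female")
  )
  for (d in setdiff(DIAGNOSES, "stable_angina")) {
    out[[paste0("diag_", d)]] <- as.numeric(baseline$diagnosis == d)
  }
  for (col in setdiff(names(baseline), fixed)) {
    out[[col]] <- as.numeric(baseline[[col]])
  }
  out
}

# Per-patient cause-specific hazard matrix for a set of transitions.
# `transitions` is a named list of list(log_base, loghr); missing covariates
# in the design raise a configuration error.
hazard_matrix <- function(transitions, design) {
  out <- vapply(transitions, function(tr) {
    lp <- rep(tr$log_base, nrow(design))
    if (length(tr$loghr)) {
      miss <- setdiff(names(tr$loghr), names(design))
      if (length(miss)) {
        stop_config(paste0("hazard covariate not in design: ",
                           paste(miss, collapse = ", ")), field = "hazard_params")
      }
      lp <- lp + as.matrix(design[names(tr$loghr)]) %*% tr$loghr
    }
    exp(as.numeric(lp))
  }, numeric(nrow(design)))
  matrix(out, nrow = nrow(design),
         dimnames = list(NULL, names(transitions)))
}

#' Simulate competing-risk events over 90-day cycles
#'
#' Cycle-by-cycle discrete competing risks: in each cycle a patient in the
#' stable state experiences at most one of the five first events, with the
#' per-cycle probability of any event `1 - exp(-H)` (H the summed
#' cause-specific rates) allocated across causes in proportion to their
#' rates. After a non-fatal first event only the two death transitions
#' remain. Non-death censoring is an independent per-cycle Bernoulli draw
#' applied to event-free cycles.
#'
#' @param baseline Baseline tibble from [generate_baseline()].
#' @param config The same [sim_config()].
#' @return A tibble of event records: `patient_id`, `event` (one of `ami`,
#'   `ischaemic_stroke`, `haemorrhagic_stroke`, `cvd_death`,
#'   `noncvd_death`, `censored`), `cycle`. Patients reaching the horizon
#'   event-free have no record. Deterministic given `config$seed`.
#' @export
simulate_events <- function(baseline, config) {
  stopifnot(inherits(config, "scad_sim_config"))
  validate_hazard_params(config$hazard_params)
  n <- nrow(baseline)
  design <- design_covariates(baseline)
  h_first <- hazard_matrix(config$hazard_params$first_event[FIRST_EVENTS], design)
  h_post <- lapply(NONFATAL_EVENTS, function(ev) {
    hazard_matrix(config$hazard_params$post_event[[ev]][DEATH_EVENTS], design)
  })
  names(h_post) <- NONFATAL_EVENTS

  H1 <- rowSums(h_first)
  p1 <- 1 - exp(-H1)
  # cumulative cause fractions for first events
  frac1 <- h_first / pmax(H1, .Machine$double.xmin)
  cum1 <- t(apply(frac1, 1, cumsum))

  Hp <- lapply(h_post, rowSums)
  pp <- lapply(Hp, function(h) 1 - exp(-h))
  frac_cvd <- Map(function(hm, h) hm[, "cvd_death"] / pmax(h, .Machine$double.xmin),
                  h_post, Hp)

  state <- rep(0L, n)   # 0 stable, 1..3 post-event index, -1 exited
  rows <- vector("list", config$horizon_cycles)
  set.seed(config$seed + 1L)
  for (cyc in seq_len(config$horizon_cycles)) {
    # fixed-size draws keep the stream independent of the cohort's state path
    u_evt <- runif(n); u_cause <- runif(n); u_cens <- runif(n)
    pid <- integer(0); evt <- character(0)

    stab <- which(state == 0L)
    if (length(stab)) {
      hit <- stab[u_evt[stab] < p1[stab]]
      if (length(hit)) {
        cause_idx <- 1L + rowSums(outer(u_cause[hit], rep(1, ncol(cum1))) > cum1[hit, , drop = FALSE])
        cause <- FIRST_EVENTS[pmin(cause_idx, length(FIRST_EVENTS))]
        pid <- c(pid, hit); evt <- c(evt, cause)
        state[hit] <- ifelse(cause %in% DEATH_EVENTS, -1L, match(cause, NONFATAL_EVENTS))
      }
    }
    for (k in seq_along(NONFATAL_EVENTS)) {
      post <- setdiff(which(state == k), pid)  # exclude same-cycle entrants
      if (length(post)) {
        hit <- post[u_evt[post] < pp[[k]][post]]
        if (length(hit)) {
          cause <- ifelse(u_cause[hit] < frac_cvd[[k]][hit], "cvd_death", "noncvd_death")
          pid <- c(pid, hit); evt <- c(evt, cause)
          state[hit] <- -1L
        }
      }
    }
    if (config$censoring_rate > 0) {
      alive <- setdiff(which(state != -1L), pid)
      cens <- alive[u_cens[alive] < config$censoring_rate]
      if (length(cens)) {
        pid <- c(pid, cens); evt <- c(evt, rep("censored", length(cens)))
        state[cens] <- -1L
      }
    }
    if (length(pid)) {
      rows[[cyc]] <- tibble::tibble(
        patient_id = baseline$patient_id[pid], event = evt, cycle = cyc
      )
    }
    if (all(state == -1L)) break
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(patient_id = integer(), event = character(), cycle = integer()))
  }
  dplyr::arrange(out, .data$patient_id, .data$cycle)
}

#' Per-patient exit cycle and reason
#'
#' Collapses the event table to one row per patient giving the last observed
#' cycle and why observation ended: CVD death, non-CVD death, transfer out
#' (non-death censoring), or administrative study end at the horizon.
#'
#' @param baseline Baseline tibble (defines the patient set).
#' @param events Event tibble from [simulate_events()].
#' @param horizon_cycles Administrative horizon (cycles).
#' @return Tibble: `patient_id`, `exit_cycle`, `exit_reason` (one of
#'   `death_cvd`, `death_noncvd`, `transfer_out`, `study_end`).
#' @export
patient_exits <- function(baseline, events, horizon_cycles) {
  unknown <- setdiff(unique(events$patient_id), baseline$patient_id)
  if (length(unknown)) {
    stop_data(paste0("events refer to unknown patient ids: ",
                     paste(head(unknown, 10), collapse = ", ")))
  }
  term <- events |>
    dplyr::filter(.data$event %in% c(DEATH_EVENTS, "censored")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$cycle, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$patient_id,
      exit_cycle = .data$cycle,
      exit_reason = dplyr::case_match(
        .data$event,
        "cvd_death" ~ "death_cvd",
        "noncvd_death" ~ "death_noncvd",
        "censored" ~ "transfer_out"
      )
    )
  tibble::tibble(patient_id = baseline$patient_id) |>
    dplyr::left_join(term, by = "patient_id") |>
    dplyr::mutate(
      exit_cycle = dplyr::coalesce(.data$exit_cycle, as.integer(horizon_cycles)),
      exit_reason = dplyr::coalesce(.data$exit_reason, "study_end")
    )
}

# First non-fatal event per patient (at most one exists by construction).
first_nonfatal <- function(events) {
  events |>
    dplyr::filter(.data$event %in% NONFATAL_EVENTS) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$cycle, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(patient_id = .data$patient_id, event_type = .data$event,
                     event_cycle = .data$cycle)
}

# Additive per-cycle category mean for a grid of patient-cycles.
# `ce` is the per-patient covariate effect sum, `cs`/`dth` describe event
# state per row.
category_mean <- function(params, cycle, ce, event_type, cycles_since, death_type) {
  m <- params$baseline + params$trend * (cycle - 1) + ce
  has_ev <- !is.na(event_type)
  if (any(has_ev)) {
    for (ev in NONFATAL_EVENTS) {
      inc <- params$event_increments[[ev]]
      if (is.null(inc)) next
      idx <- which(has_ev & event_type == ev)
      if (!length(idx)) next
      b <- cycles_since[idx]
      m[idx] <- m[idx] + ifelse(b <= 3, inc$bands[b + 1], inc$long_run)
    }
  }
  has_d <- !is.na(death_type)
  if (any(has_d)) {
    m[has_d] <- m[has_d] + params$death_increments[death_type[has_d]]
  }
  m
}

#' Simulate 90-day period costs
#'
#' Produces one row per patient per observed cycle (up to and including the
#' exit cycle). The mean of each cost category follows the ground-truth
#' additive structure (baseline + trend + covariate effects + time-since-
#' event band increment + death-cycle increment); components are drawn as
#' independent gammas with those means (shape `config$gamma_shape`,
#' scale = mean/shape) and recomposed so that the category composition
#' invariants hold row by row: CHD inpatient <= CVD inpatient <= total
#' inpatient and CVD drugs <= total drugs. Utilization counters
#' (hospitalizations, stays, length of stay, consultations,
#' revascularizations, drug flags) are generated alongside.
#'
#' @param baseline Baseline tibble.
#' @param events Event tibble from [simulate_events()].
#' @param config The [sim_config()].
#' @return A period-cost tibble (one row per patient-cycle). Deterministic
#'   given `config$seed`.
#' @export
simulate_costs <- function(baseline, events, config) {
  stopifnot(inherits(config, "scad_sim_config"))
  exits <- patient_exits(baseline, events, config$horizon_cycles)
  fe <- first_nonfatal(events)
  design <- design_covariates(baseline)

  # per-patient covariate effect sums for each category
  cov_effect <- function(params) {
    eff <- params$covariate_effects
    if (!length(eff)) return(rep(0, nrow(design)))
    miss <- setdiff(names(eff), names(design))
    if (length(miss)) {
      stop_config(paste0("cost covariate not in design: ", paste(miss, collapse = ", ")),
                  field = "cost_params")
    }
    as.numeric(as.matrix(design[names(eff)]) %*% eff)
  }
  ce <- lapply(config$cost_params, cov_effect)

  grid <- tibble::tibble(
    patient_id = rep(exits$patient_id, exits$exit_cycle),
    cycle = sequence(exits$exit_cycle),
    row_idx = rep(seq_len(nrow(exits)), exits$exit_cycle)
  ) |>
    dplyr::left_join(fe, by = "patient_id") |>
    dplyr::left_join(
      exits |> dplyr::filter(startsWith(.data$exit_reason, "death")) |>
        dplyr::transmute(.data$patient_id, death_cycle = .data$exit_cycle,
                         death_type = sub("death_", "", .data$exit_reason)),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      cycles_since = ifelse(!is.na(.data$event_cycle) & .data$cycle >= .data$event_cycle,
                            .data$cycle - .data$event_cycle, NA_integer_),
      event_type = ifelse(is.na(.data$cycles_since), NA_character_, .data$event_type),
      death_type = ifelse(!is.na(.data$death_cycle) & .data$cycle == .data$death_cycle,
                          paste0(.data$death_type, "_death"), NA_character_)
    )

  idx <- grid$row_idx
  m_cat <- lapply(COST_CATEGORIES, function(cat) {
    category_mean(config$cost_params[[cat]], grid$cycle, ce[[cat]][idx],
                  grid$event_type, grid$cycles_since, grid$death_type)
  })
  names(m_cat) <- COST_CATEGORIES

  cc <- config$cost_components
  shared <- cc[["primary_care"]] + cc[["diagnostics"]] + cc[["drugs_cvd"]]
  m_inpat_chd <- m_cat$chd - shared
  m_cvd_extra <- m_cat$cvd - m_cat$chd
  m_noncvd_extra <- m_cat$total - m_cat$cvd - cc[["drugs_noncvd"]]
  for (nm in c("m_inpat_chd", "m_cvd_extra", "m_noncvd_extra")) {
    v <- get(nm)
    if (any(v < -1e-9)) {
      stop_config(paste0(
        "cost parameters imply a negative component mean (", nm,
        " down to ", sprintf("%.2f", min(v)),
        "); keep category means nested and non-negative"), field = "cost_params")
    }
  }

  set.seed(config$seed + 2L)
  draw <- function(m) {
    m <- pmax(m, 0)
    if (is.infinite(config$gamma_shape)) return(m)
    out <- numeric(length(m))
    pos <- m > 0
    out[pos] <- rgamma(sum(pos), shape = config$gamma_shape,
                       scale = m[pos] / config$gamma_shape)
    out
  }
  nrows <- nrow(grid)
  pc <- draw(rep(cc[["primary_care"]], nrows))
  dg <- draw(rep(cc[["diagnostics"]], nrows))
  dr_cvd <- draw(rep(cc[["drugs_cvd"]], nrows))
  dr_non <- draw(rep(cc[["drugs_noncvd"]], nrows))
  in_chd <- draw(m_inpat_chd)
  in_cvdx <- draw(m_cvd_extra)
  in_nonx <- draw(m_noncvd_extra)

  inpatient_chd <- in_chd
  inpatient_cvd <- in_chd + in_cvdx
  inpatient_total <- inpatient_cvd + in_nonx

  # utilization counters: stays scale with inpatient spending, LOS with
  # stays; drug flags are patient-level; revascularization peaks in the
  # event band.
  stays_chd <- rpois(nrows, pmax(m_inpat_chd, 0) / 2500)
  stays_cvd <- stays_chd + rpois(nrows, pmax(m_cvd_extra, 0) / 2500)
  stays_total <- stays_cvd + rpois(nrows, pmax(m_noncvd_extra, 0) / 2500)
  los <- function(stays, mean_los) ifelse(stays > 0, rpois(nrows, stays * mean_los), 0L)
  in_band1 <- !is.na(grid$cycles_since) & grid$cycles_since == 0

  n <- nrow(baseline)
  set.seed(config$seed + 3L)
  on_cvd_drug_p <- as.integer(runif(n) < 0.882)
  on_any_drug_p <- pmax(on_cvd_drug_p, as.integer(runif(n) < 0.25))
  on_antiplatelet_p <- as.integer(runif(n) < 0.656)
  on_betablocker_p <- as.integer(runif(n) < 0.46)

  tibble::tibble(
    patient_id = grid$patient_id,
    cycle = grid$cycle,
    inpatient_total = inpatient_total,
    inpatient_cvd = inpatient_cvd,
    inpatient_chd = inpatient_chd,
    primary_care = pc,
    diagnostics = dg,
    drugs_total = dr_cvd + dr_non,
    drugs_cvd = dr_cvd,
    stays_total = stays_total,
    stays_cvd = stays_cvd,
    stays_chd = stays_chd,
    los_total = los(stays_total, 6.7),
    los_cvd = los(stays_cvd, 7.5),
    los_chd = los(stays_chd, 4.6),
    consultations = rpois(nrows, 2.7),
    pci = as.integer(runif(nrows) < 0.004 + 0.06 * in_band1),
    cabg = as.integer(runif(nrows) < 0.003 + 0.03 * in_band1),
    on_any_drug = on_any_drug_p[idx],
    on_cvd_drug = on_cvd_drug_p[idx],
    on_antiplatelet = on_antiplatelet_p[idx],
    on_betablocker = on_betablocker_p[idx]
  )
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [generate_baseline()], [simulate_events()],
#' and [simulate_costs()] in sequence, optionally writing the three
#' delimited tables (`baseline.csv`, `events.csv`, `period_costs.csv`).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for the three CSV files (created if
#'   needed; writes are atomic).
#' @return A list with `baseline`, `events`, and `panel` tibbles plus the
#'   `config` used.
#' @export
simulate_scad_cohort <- function(config, out_dir = NULL) {
  baseline <- generate_baseline(config)
  events <- simulate_events(baseline, config)
  panel <- simulate_costs(baseline, events, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_atomic(baseline, file.path(out_dir, "baseline.csv"))
    write_csv_atomic(events, file.path(out_dir, "events.csv"))
    write_csv_atomic(panel, file.path(out_dir, "period_costs.csv"))
  }
  list(baseline = baseline, events = events, panel = panel, config = config)
}
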