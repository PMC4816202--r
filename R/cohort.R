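# Cohort entry rules and analysis-window derivation.

#' Derive the cohort entry date
#'
#' Entry into the stable coronary artery disease cohort starts at the date
#' of diagnosis for stable angina or unspecified CHD, and 182 days (six
#' months, as a fixed offset for reproducibility) after the diagnosis for
#' an acute coronary syndrome (unstable angina, STEMI, NSTEMI), separating
#' long-term prognosis from the high-risk post-acute period.
#'
#' @param diagnosis_date A `Date` vector.
#' @param diagnosis A character vector of diagnosis categories (see
#'   `DIAGNOSES`); recycled against `diagnosis_date`.
#' @return A `Date` vector of entry dates.
#' @export
#' @examples
#' derive_entry_date(as.Date("2005-01-01"), "stable_angina") # unchanged
#' derive_entry_date(as.Date("2005-01-01"), "nstemi")        # + 182 days
derive_entry_date <- function(diagnosis_date, diagnosis) {
  if (!inherits(diagnosis_date, "Date")) {
    stop_data("`diagnosis_date` must be a Date vector")
  }
  bad <- setdiff(unique(diagnosis), DIAGNOSES)
  if (length(bad)) {
    stop_data(paste0("unknown diagnosis category: ", paste(bad, collapse = ", ")))
  }
  acs <- diagnosis %in% c("unstable_angina", "stemi", "nstemi")
  diagnosis_date + ifelse(acs, 182L, 0L)
}

#' Build first-year and post-event analysis windows
#'
#' Derives, per patient, the four-cycle (360-day) analysis windows used by
#' the cost and utilization summaries: one `first_scad_year` window (cycles
#' 1-4) for every patient, and one `first_post_event_year` window (the
#' event cycle and the three following cycles) for every patient whose
#' first event is non-fatal. A window is `complete` when follow-up covers
#' it fully or ends within it by death; windows cut short by non-death
#' censoring (transfer out, administrative end) are incomplete and excluded
#' from downstream summaries.
#'
#' @param baseline Baseline tibble.
#' @param events Event tibble.
#' @param horizon_cycles Administrative follow-up horizon (cycles).
#' @return Tibble: `patient_id`, `window_kind`, `start_cycle`, `end_cycle`,
#'   `complete`, `index_event_type` (`"none"` for the first-year window).
#' @export
build_analysis_windows <- function(baseline, events, horizon_cycles) {
  exits <- patient_exits(baseline, events, horizon_cycles)
  died <- startsWith(exits$exit_reason, "death")

  first_year <- tibble::tibble(
    patient_id = exits$patient_id,
    window_kind = "first_scad_year",
    start_cycle = 1L,
    end_cycle = 4L,
    complete = exits$exit_cycle >= 4L | died,
    index_event_type = "none"
  )

  fe <- first_nonfatal(events) |>
    dplyr::left_join(exits, by = "patient_id")
  post_event <- tibble::tibble(
    patient_id = fe$patient_id,
    window_kind = "first_post_event_year",
    start_cycle = fe$event_cycle,
    end_cycle = fe$event_cycle + 3L,
    complete = fe$exit_cycle >= fe$event_cycle + 3L | startsWith(fe$exit_reason, "death"),
    index_event_type = fe$event_type
  )

  dplyr::bind_rows(first_year, post_event) |>
    dplyr::arrange(.data$patient_id, .data$window_kind)
}
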