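# Cost-category composition and window-level cost / utilization summaries.

#' Compose total, CVD, and CHD cost categories
#'
#' The three nested cost categories are: total healthcare costs (all costs
#' incurred); CVD costs (CVD-related hospitalization costs, CVD-related
#' drugs, and all primary care and diagnostic costs); and CHD costs
#' (CHD-related hospitalization costs, CVD-related drugs, and all primary
#' care and diagnostic costs). CHD hospitalizations are a subset of CVD
#' hospitalizations, so chd <= cvd <= total row by row.
#'
#' @param rows A period-cost tibble with columns `inpatient_total`,
#'   `inpatient_cvd`, `inpatient_chd`, `primary_care`, `diagnostics`,
#'   `drugs_total`, `drugs_cvd`.
#' @return The input with `total_cost`, `cvd_cost`, `chd_cost` columns
#'   appended.
#' @export
#' @examples
#' compose_cost_categories(tibble::tibble(
#'   inpatient_total = 2018, inpatient_cvd = 1487, inpatient_chd = 1067,
#'   primary_care = 466, diagnostics = 141, drugs_total = 508, drugs_cvd = 105
#' ))
compose_cost_categories <- function(rows) {
  comp <- c("inpatient_total", "inpatient_cvd", "inpatient_chd",
            "primary_care", "diagnostics", "drugs_total", "drugs_cvd")
  miss <- setdiff(comp, names(rows))
  if (length(miss)) {
    stop_data(paste0("missing cost component columns: ", paste(miss, collapse = ", ")))
  }
  for (col in comp) {
    if (any(rows[[col]] < 0, na.rm = TRUE)) {
      stop_data(paste0("negative cost component in `", col, "`"))
    }
  }
  if (any(rows$inpatient_chd > rows$inpatient_cvd + 1e-9) ||
      any(rows$inpatient_cvd > rows$inpatient_total + 1e-9) ||
      any(rows$drugs_cvd > rows$drugs_total + 1e-9)) {
    stop_data("cost components violate nesting: need inpatient_chd <= inpatient_cvd <= inpatient_total and drugs_cvd <= drugs_total")
  }
  dplyr::mutate(
    rows,
    total_cost = .data$inpatient_total + .data$primary_care + .data$diagnostics +
      .data$drugs_total,
    cvd_cost = .data$inpatient_cvd + .data$primary_care + .data$diagnostics +
      .data$drugs_cvd,
    chd_cost = .data$inpatient_chd + .data$primary_care + .data$diagnostics +
      .data$drugs_cvd
  )
}

#' Share of a cost category, as a percentage
#'
#' Shares are ratios of means (100 * mean(part) / mean(total)), not means of
#' per-patient ratios, and are rounded half-up to one decimal to match
#' conventional reporting.
#'
#' @param part,total Mean costs (GBP); `part` may be a vector.
#' @param digits Decimal places (default 1).
#' @return Percentage(s) in `[0, 100]` for nested categories.
#' @export
#' @examples
#' cost_share(1780, 3133) # 56.8
cost_share <- function(part, total, digits = 1) {
  if (any(total <= 0)) stop_data("`total` mean must be positive")
  round_half_up(100 * part / total, digits)
}

# Per-patient window totals for every cost component and composed category.
window_patient_totals <- function(panel, windows, window_kind) {
  w <- windows |>
    dplyr::filter(.data$window_kind == !!window_kind, .data$complete)
  if (nrow(w) == 0) return(w["patient_id"])
  comp <- c("inpatient_total", "inpatient_cvd", "inpatient_chd",
            "primary_care", "diagnostics", "drugs_total", "drugs_cvd")
  rows <- panel |>
    dplyr::inner_join(w[c("patient_id", "start_cycle", "end_cycle")],
                      by = "patient_id") |>
    dplyr::filter(.data$cycle >= .data$start_cycle, .data$cycle <= .data$end_cycle) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(comp), sum), .groups = "drop")
  # patients who die early in a complete window have fewer cycles; patients
  # with no rows in range contribute zeros
  w["patient_id"] |>
    dplyr::left_join(rows, by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(comp), ~ dplyr::coalesce(.x, 0))) |>
    compose_cost_categories()
}

#' Summarize window costs
#'
#' Computes, over complete analysis windows of one kind, the per-patient
#' annual (four-cycle) totals of every cost component and the composed
#' total/CVD/CHD categories, then their mean, SD (n-1 denominator),
#' median and interquartile range, and each component's share of mean total
#' cost.
#'
#' @param panel Period-cost tibble.
#' @param windows Window tibble from [build_analysis_windows()].
#' @param window_kind `"first_scad_year"` or `"first_post_event_year"`.
#' @return A tibble with one row per component: `window_kind`, `n`,
#'   `component`, `mean`, `sd`, `median`, `q25`, `q75`, `share_pct`. Empty
#'   window sets yield a zero-row tibble of the same shape.
#' @export
summarize_costs <- function(panel, windows, window_kind = "first_scad_year") {
  window_kind <- match.arg(window_kind, c("first_scad_year", "first_post_event_year"))
  totals <- window_patient_totals(panel, windows, window_kind)
  cols <- c("total_cost", "cvd_cost", "chd_cost",
            "inpatient_total", "inpatient_cvd", "inpatient_chd",
            "primary_care", "diagnostics", "drugs_total", "drugs_cvd")
  empty <- tibble::tibble(
    window_kind = character(), n = integer(), component = character(),
    mean = numeric(), sd = numeric(), median = numeric(),
    q25 = numeric(), q75 = numeric(), share_pct = numeric()
  )
  if (nrow(totals) == 0) return(empty)
  mean_total <- mean(totals$total_cost)
  purrr::map_dfr(cols, function(col) {
    x <- totals[[col]]
    tibble::tibble(
      window_kind = window_kind, n = nrow(totals), component = col,
      mean = mean(x), sd = sd(x), median = median(x),
      q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)),
      share_pct = cost_share(mean(x), mean_total)
    )
  })
}

#' Summarize window healthcare utilization
#'
#' Over complete windows of one kind: percentages of patients with at least
#' one hospitalization (any / CVD / CHD), unconditional mean inpatient
#' stays, conditional mean stays and mean length of stay per stay among the
#' hospitalized, mean primary care consultations, revascularization
#' percentages (any / PCI / CABG), and drug-class percentages.
#'
#' @inheritParams summarize_costs
#' @return A tibble: `window_kind`, `n`, `measure`, `value`, and
#'   `n_basis` (the denominator: all patients or the hospitalized subset).
#' @export
summarize_utilization <- function(panel, windows, window_kind = "first_scad_year") {
  window_kind <- match.arg(window_kind, c("first_scad_year", "first_post_event_year"))
  w <- windows |>
    dplyr::filter(.data$window_kind == !!window_kind, .data$complete)
  empty <- tibble::tibble(window_kind = character(), n = integer(),
                          measure = character(), value = numeric(),
                          n_basis = integer())
  if (nrow(w) == 0) return(empty)
  util_cols <- c("stays_total", "stays_cvd", "stays_chd",
                 "los_total", "los_cvd", "los_chd",
                 "consultations", "pci", "cabg",
                 "on_any_drug", "on_cvd_drug", "on_antiplatelet", "on_betablocker")
  present <- intersect(util_cols, names(panel))
  per <- panel |>
    dplyr::inner_join(w[c("patient_id", "start_cycle", "end_cycle")],
                      by = "patient_id") |>
    dplyr::filter(.data$cycle >= .data$start_cycle, .data$cycle <= .data$end_cycle) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(present), sum), .groups = "drop")
  per <- w["patient_id"] |>
    dplyr::left_join(per, by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(present), ~ dplyr::coalesce(.x, 0)))
  n <- nrow(per)

  add <- function(acc, measure, value, n_basis = n) {
    dplyr::bind_rows(acc, tibble::tibble(window_kind = window_kind, n = n,
                                         measure = measure, value = value,
                                         n_basis = as.integer(n_basis)))
  }
  out <- empty
  for (cat in c("total", "cvd", "chd")) {
    stays <- per[[paste0("stays_", cat)]]
    losd <- per[[paste0("los_", cat)]]
    hosp <- stays > 0
    out <- add(out, paste0("hospitalized_", cat, "_pct"), 100 * mean(hosp))
    out <- add(out, paste0("stays_", cat, "_mean"), mean(stays))
    if (any(hosp)) {
      out <- add(out, paste0("stays_", cat, "_mean_hospitalized"),
                 mean(stays[hosp]), sum(hosp))
      out <- add(out, paste0("los_", cat, "_per_stay_hospitalized"),
                 mean(losd[hosp] / stays[hosp]), sum(hosp))
    } else {
      out <- add(out, paste0("stays_", cat, "_mean_hospitalized"), 0, 0)
      out <- add(out, paste0("los_", cat, "_per_stay_hospitalized"), 0, 0)
    }
  }
  if ("consultations" %in% present) {
    out <- add(out, "consultations_mean", mean(per$consultations))
  }
  if (all(c("pci", "cabg") %in% present)) {
    out <- add(out, "revascularized_pct", 100 * mean(per$pci + per$cabg > 0))
    out <- add(out, "pci_pct", 100 * mean(per$pci > 0))
    out <- add(out, "cabg_pct", 100 * mean(per$cabg > 0))
  }
  for (dc in intersect(c("on_any_drug", "on_cvd_drug", "on_antiplatelet",
                         "on_betablocker"), present)) {
    out <- add(out, paste0(dc, "_pct"), 100 * mean(per[[dc]] > 0))
  }
  out
}
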