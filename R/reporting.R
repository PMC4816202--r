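# Risk-decile stratification, representative profiles, report tables, and
# the end-to-end pipeline driver.

#' Assign cardiovascular risk deciles
#'
#' Computes every patient's modelled five-year risk of a first
#' cardiovascular event (AMI, stroke, or CVD death) under the fitted
#' transition hazards, ranks patients, and splits them into ten
#' near-equal groups (sizes differ by at most one; ties broken by patient
#' id). Decile 1 is the lowest risk.
#'
#' @param baseline Baseline tibble (at least 10 patients).
#' @param params A `transition_params` (or coercible).
#' @param cycles Risk horizon in cycles (default 20 = five years).
#' @return `baseline` with `five_year_risk` and `decile` columns appended.
#' @export
assign_deciles <- function(baseline, params, cycles = 20) {
  n <- nrow(baseline)
  if (n < 10) stop_data("need at least 10 patients to form deciles")
  risk <- five_year_risk_cohort(params, baseline, cycles)
  ord <- order(risk, baseline$patient_id)
  sizes <- rep(n %/% 10, 10)
  if (n %% 10) sizes[seq_len(n %% 10)] <- sizes[seq_len(n %% 10)] + 1L
  decile <- integer(n)
  decile[ord] <- rep(1:10, times = sizes)
  baseline |>
    dplyr::mutate(five_year_risk = risk, decile = decile)
}

#' Representative covariate profile of a patient group
#'
#' Continuous covariates are averaged; binary covariates enter as
#' prevalences (fractional covariate values), which preserves the group's
#' average linear predictor better than modal values. Missing biomarker
#' values are ignored in the means.
#'
#' @param members Baseline rows of one group (non-empty).
#' @return A one-row tibble of design covariates (see
#'   [design_covariates()]) plus `age_at_entry`.
#' @export
representative_profile <- function(members) {
  if (!nrow(members)) stop_data("cannot build a profile from an empty group")
  design <- design_covariates(members)
  prof <- dplyr::summarise(design,
                           dplyr::across(dplyr::everything(),
                                         ~ mean(.x, na.rm = TRUE)))
  prof$age_at_entry <- mean(members$age_at_entry)
  prof
}

#' Representative profiles for the ten risk deciles
#'
#' @param deciled Output of [assign_deciles()].
#' @return A tibble with one row per decile: `decile`, `n`, `mean_age`,
#'   `mean_risk`, and a `profile` list-column of one-row covariate tibbles.
#' @export
decile_profiles <- function(deciled) {
  deciled |>
    dplyr::group_by(.data$decile) |>
    dplyr::group_map(function(members, key) {
      tibble::tibble(
        decile = key$decile,
        n = nrow(members),
        mean_age = mean(members$age_at_entry),
        mean_risk = mean(members$five_year_risk),
        profile = list(representative_profile(members))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$decile)
}

#' Build the decile cost report table
#'
#' One row per risk decile: five-year risk (percent, 2 decimals), average
#' age, life expectancy (years), and 5-year and lifetime total/CVD/CHD
#' costs, discounted and undiscounted (GBP, rounded to the nearest pound),
#' plus CHD/total and CVD/total share percentages (1 decimal) for the
#' undiscounted cells.
#'
#' @param profiles Output of [decile_profiles()] (10 rows).
#' @param projections Named or positional list of 10 [project()] results,
#'   one per decile.
#' @return A tibble with one row per decile.
#' @export
build_table3 <- function(profiles, projections) {
  if (nrow(profiles) != 10) stop_data("expected 10 decile profiles")
  purrr::map_dfr(seq_len(10), function(d) {
    pr <- projections[[d]]
    if (is.null(pr)) stop_data(paste0("missing projection for decile ", d))
    cells <- function(tab, label) {
      out <- list()
      for (cat in COST_CATEGORIES) {
        row <- tab[tab$category == cat, ]
        out[[paste0(label, "_", cat)]] <- round_half_up(row$undiscounted)
        out[[paste0(label, "_", cat, "_disc")]] <- round_half_up(row$discounted)
      }
      out
    }
    fy <- cells(pr$five_year, "cost_5yr")
    lt <- cells(pr$lifetime, "cost_lifetime")
    tibble::as_tibble(c(
      list(
        decile = d,
        five_year_risk_pct = round_half_up(100 * pr$five_year_risk, 2),
        mean_age = round_half_up(profiles$mean_age[profiles$decile == d]),
        life_expectancy = round_half_up(pr$life_expectancy, 2)
      ),
      fy, lt,
      list(
        share_5yr_chd_pct = cost_share(fy$cost_5yr_chd, fy$cost_5yr_total),
        share_5yr_cvd_pct = cost_share(fy$cost_5yr_cvd, fy$cost_5yr_total),
        share_lifetime_chd_pct = cost_share(lt$cost_lifetime_chd, lt$cost_lifetime_total),
        share_lifetime_cvd_pct = cost_share(lt$cost_lifetime_cvd, lt$cost_lifetime_total)
      )
    ))
  })
}

#' Per-decile cost and survival curves
#'
#' The per-cycle cumulative expected costs (undiscounted, by category) and
#' survival for each decile's representative profile: the data behind the
#' cost-over-time figure.
#'
#' @param projections List of [project()] results (one per decile).
#' @return A tibble: `decile`, `cycle`, `years`, `survival`,
#'   `cum_total`, `cum_cvd`, `cum_chd`.
#' @export
cost_curves <- function(projections) {
  purrr::imap_dfr(projections, function(pr, d) {
    tibble::tibble(
      decile = as.integer(d),
      cycle = seq_len(pr$horizon_cycles),
      years = .data$cycle * CYCLE_YEARS,
      survival = pr$survival,
      cum_total = cumsum(pr$cost_streams$total),
      cum_cvd = cumsum(pr$cost_streams$cvd),
      cum_chd = cumsum(pr$cost_streams$chd)
    )
  })
}

#' Plot decile cost and survival curves
#'
#' @param curves Output of [cost_curves()].
#' @param deciles Which deciles to draw (default 1, 4, 7, 10).
#' @return A ggplot object.
#' @export
plot_cost_curves <- function(curves, deciles = c(1, 4, 7, 10)) {
  df <- curves |>
    dplyr::filter(.data$decile %in% deciles) |>
    tidyr::pivot_longer(c("cum_total", "cum_cvd", "cum_chd", "survival"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(
      panel = ifelse(.data$series == "survival", "Survival",
                     "Cumulative cost (GBP)"),
      decile = factor(.data$decile)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$years, .data$value,
                                   colour = .data$decile,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Years since cohort entry", y = NULL,
                  colour = "Risk decile", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Export pipeline outputs
#'
#' Writes the report tables produced by [run_scad_analysis()] as headered
#' CSV files plus a JSON metadata record (seed, conventions, problem
#' sizes). All writes are atomic (temp file then rename), so reruns with
#' the same configuration and seed produce byte-identical files.
#'
#' @param results A [run_scad_analysis()] result list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    abort(paste0("output directory is not writable: ", out_dir),
          class = "scadcost_io_error")
  }
  files <- c(
    table1 = "table1.csv", table2 = "table2.csv",
    forest_plot = "forest_plot.csv", table3 = "table3.csv",
    cost_curves = "cost_curves.csv"
  )
  for (nm in names(files)) {
    write_csv_atomic(results[[nm]], file.path(out_dir, files[[nm]]))
  }
  write_json_atomic(results$metadata, file.path(out_dir, "run_metadata.json"))
  invisible(file.path(out_dir, c(files, "run_metadata.json")))
}

#' Run the full SCAD cost analysis pipeline
#'
#' End-to-end driver: simulate (or accept) a cohort; derive analysis
#' windows; summarize utilization and costs for the first SCAD year and
#' the first post-event year; fit the first-year gamma cost regression on
#' multiply imputed data and report natural-scale increments; fit the
#' three-category 90-day panel cost model; fit the transition hazards;
#' assign risk deciles, build representative profiles, and project 5-year
#' and lifetime costs per decile.
#'
#' @param config A [sim_config()].
#' @param cohort Optional pre-simulated cohort (list with `baseline`,
#'   `events`, `panel`); by default simulated from `config`.
#' @param m Number of imputations for the cost regression.
#' @param horizon_cycles Projection horizon.
#' @param rate Annual discount rate.
#' @param panel_covariates Covariates in the panel cost model.
#' @param transition_covariates Covariates in the transition model.
#' @param out_dir Optional output directory passed to [export_outputs()].
#' @return A list: `cohort`, `windows`, `table1`, `table2`, `regression`
#'   (pooled fit and effects), `forest_plot`, `panel_fits`, `transitions`,
#'   `deciles`, `profiles`, `projections`, `table3`, `cost_curves`,
#'   `metadata`.
#' @export
run_scad_analysis <- function(config,
                              cohort = NULL,
                              m = 5,
                              horizon_cycles = 400,
                              rate = 0.035,
                              panel_covariates = c("age10c", "sex_female"),
                              transition_covariates = c("age10c", "sex_female"),
                              out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_scad_cohort(config)
  baseline <- cohort$baseline; events <- cohort$events; panel <- cohort$panel

  windows <- build_analysis_windows(baseline, events, config$horizon_cycles)
  table1 <- dplyr::bind_rows(
    summarize_utilization(panel, windows, "first_scad_year"),
    summarize_utilization(panel, windows, "first_post_event_year")
  )
  table2 <- dplyr::bind_rows(
    summarize_costs(panel, windows, "first_scad_year"),
    summarize_costs(panel, windows, "first_post_event_year")
  )

  totals <- window_patient_totals(panel, windows, "first_scad_year") |>
    dplyr::select(dplyr::all_of(c("patient_id", "total_cost")))
  regression <- fit_first_year_costs(baseline, totals, m = m, seed = config$seed)

  design <- build_design_panel(panel, events, baseline, covariates = panel_covariates)
  panel_fits <- lapply(setNames(COST_CATEGORIES, COST_CATEGORIES), function(cat) {
    fit_panel(design, cat, covariates = panel_covariates)
  })

  transitions <- fit_transitions(baseline, events, config$horizon_cycles,
                                 covariates = transition_covariates)

  deciled <- assign_deciles(baseline, transitions)
  profiles <- decile_profiles(deciled)
  projections <- lapply(profiles$profile, function(prof) {
    project(transitions, panel_fits, prof, horizon_cycles = horizon_cycles,
            rate = rate)
  })
  table3 <- build_table3(profiles, projections)
  curves <- cost_curves(projections)

  results <- list(
    cohort = cohort, windows = windows,
    table1 = table1, table2 = table2,
    regression = regression, forest_plot = regression$effects,
    panel_fits = panel_fits, transitions = transitions,
    deciles = deciled[c("patient_id", "five_year_risk", "decile")],
    profiles = profiles, projections = projections,
    table3 = table3, cost_curves = curves,
    metadata = list(
      seed = config$seed,
      n_patients = config$n_patients,
      follow_up_cycles = config$horizon_cycles,
      projection_horizon_cycles = horizon_cycles,
      discount_rate = rate,
      discount_timing = "mid",
      imputations = m,
      cycle_days = CYCLE_DAYS,
      year_days = YEAR_DAYS
    )
  )
  if (!is.null(out_dir)) export_outputs(results, out_dir)
  results
}
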