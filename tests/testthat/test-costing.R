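test_that("category composition reproduces the reference cost tables", {
  first_year <- tibble::tibble(
    inpatient_total = 2018, inpatient_cvd = 1487, inpatient_chd = 1067,
    primary_care = 466, diagnostics = 141, drugs_total = 508, drugs_cvd = 105
  )
  out <- compose_cost_categories(first_year)
  expect_equal(out$total_cost, 3133)
  expect_equal(out$cvd_cost, 2199)
  expect_equal(out$chd_cost, 1779)

  post_event <- tibble::tibble(
    inpatient_total = 8744, inpatient_cvd = 7957, inpatient_chd = 5910,
    primary_care = 589, diagnostics = 228, drugs_total = 816, drugs_cvd = 142
  )
  out2 <- compose_cost_categories(post_event)
  expect_equal(out2$total_cost, 10377)
  expect_equal(out2$cvd_cost, 8916)
  expect_equal(out2$chd_cost, 6869)

  zeros <- first_year |> dplyr::mutate(dplyr::across(dplyr::everything(), ~0))
  outz <- compose_cost_categories(zeros)
  expect_equal(c(outz$total_cost, outz$cvd_cost, outz$chd_cost), c(0, 0, 0))
})

test_that("composition rejects negative or non-nested components", {
  row <- tibble::tibble(
    inpatient_total = 100, inpatient_cvd = 80, inpatient_chd = 60,
    primary_care = 10, diagnostics = 5, drugs_total = 20, drugs_cvd = 5
  )
  expect_error(compose_cost_categories(dplyr::mutate(row, primary_care = -1)),
               class = "scadcost_data_error")
  expect_error(compose_cost_categories(dplyr::mutate(row, inpatient_chd = 90)),
               class = "scadcost_data_error")
  expect_error(compose_cost_categories(dplyr::mutate(row, drugs_cvd = 30)),
               class = "scadcost_data_error")
  expect_error(compose_cost_categories(dplyr::select(row, -diagnostics)),
               class = "scadcost_data_error")
})

test_that("shares are ratios of means rounded half-up to one decimal", {
  expect_equal(cost_share(1780, 3133), 56.8)
  expect_equal(cost_share(2199, 3133), 70.2)
  expect_error(cost_share(10, 0), class = "scadcost_data_error")
})

test_that("a constant-cost panel summarizes to an exact annual total", {
  panel <- tidyr::expand_grid(patient_id = 1:3, cycle = 1:4) |>
    dplyr::mutate(inpatient_total = 50, inpatient_cvd = 30, inpatient_chd = 20,
                  primary_care = 25, diagnostics = 10, drugs_total = 15,
                  drugs_cvd = 5)
  windows <- tibble::tibble(patient_id = 1:3, window_kind = "first_scad_year",
                            start_cycle = 1L, end_cycle = 4L, complete = TRUE,
                            index_event_type = "none")
  s <- summarize_costs(panel, windows, "first_scad_year")
  tot <- s[s$component == "total_cost", ]
  expect_equal(tot$mean, 400)
  expect_equal(tot$sd, 0)
  expect_equal(tot$n, 3L)
  expect_equal(tot$share_pct, 100)
})

test_that("summary means and shares match a brute-force re-aggregation", {
  cfg <- quick_config(n = 800, seed = 43)
  cohort <- simulate_scad_cohort(cfg)
  w <- build_analysis_windows(cohort$baseline, cohort$events, cfg$horizon_cycles)
  s <- summarize_costs(cohort$panel, w, "first_scad_year")

  # oracle: raw base-R aggregation over the same complete windows
  keep <- w$patient_id[w$window_kind == "first_scad_year" & w$complete]
  sub <- cohort$panel[cohort$panel$patient_id %in% keep & cohort$panel$cycle <= 4, ]
  tot_row <- sub$inpatient_total + sub$primary_care + sub$diagnostics +
    sub$drugs_total
  chd_row <- sub$inpatient_chd + sub$primary_care + sub$diagnostics +
    sub$drugs_cvd
  per_tot <- tapply(tot_row, sub$patient_id, sum)
  per_tot <- per_tot[match(keep, names(per_tot))]
  per_tot[is.na(per_tot)] <- 0
  per_chd <- tapply(chd_row, sub$patient_id, sum)
  per_chd <- per_chd[match(keep, names(per_chd))]
  per_chd[is.na(per_chd)] <- 0

  expect_equal(s$mean[s$component == "total_cost"], mean(per_tot))
  expect_equal(s$sd[s$component == "total_cost"], stats::sd(per_tot))
  expect_equal(s$median[s$component == "total_cost"], stats::median(per_tot))
  expect_equal(s$share_pct[s$component == "chd_cost"],
               round(100 * mean(per_chd) / mean(per_tot), 1))
  # mean(total) decomposes into component means
  comp_sum <- sum(s$mean[s$component %in% c("inpatient_total", "primary_care",
                                            "diagnostics", "drugs_total")])
  expect_equal(s$mean[s$component == "total_cost"], comp_sum)
  # category ordering
  expect_true(s$mean[s$component == "chd_cost"] <=
                s$mean[s$component == "cvd_cost"])
  expect_true(s$mean[s$component == "cvd_cost"] <=
                s$mean[s$component == "total_cost"])
})

test_that("empty window sets yield an empty summary rather than an error", {
  panel <- tibble::tibble(patient_id = integer(), cycle = integer(),
                          inpatient_total = numeric(), inpatient_cvd = numeric(),
                          inpatient_chd = numeric(), primary_care = numeric(),
                          diagnostics = numeric(), drugs_total = numeric(),
                          drugs_cvd = numeric())
  windows <- tibble::tibble(patient_id = integer(), window_kind = character(),
                            start_cycle = integer(), end_cycle = integer(),
                            complete = logical(), index_event_type = character())
  s <- summarize_costs(panel, windows, "first_scad_year")
  expect_equal(nrow(s), 0)
  u <- summarize_utilization(panel, windows, "first_scad_year")
  expect_equal(nrow(u), 0)
})

test_that("utilization summary handles hand-computable cases", {
  windows <- tibble::tibble(patient_id = 1L, window_kind = "first_scad_year",
                            start_cycle = 1L, end_cycle = 4L, complete = TRUE,
                            index_event_type = "none")
  base_cols <- tibble::tibble(
    patient_id = 1L, cycle = 1:4,
    inpatient_total = 0, inpatient_cvd = 0, inpatient_chd = 0,
    primary_care = 0, diagnostics = 0, drugs_total = 0, drugs_cvd = 0
  )
  # no hospital activity at all
  quiet <- base_cols |>
    dplyr::mutate(stays_total = 0L, stays_cvd = 0L, stays_chd = 0L,
                  los_total = 0L, los_cvd = 0L, los_chd = 0L,
                  consultations = 2L, pci = 0L, cabg = 0L)
  u0 <- summarize_utilization(quiet, windows, "first_scad_year")
  pct <- u0$value[grepl("hospitalized_.*_pct", u0$measure)]
  expect_true(all(pct == 0))
  expect_equal(u0$value[u0$measure == "consultations_mean"], 8)

  # one patient, 2 CHD stays of 3 and 5 days
  busy <- base_cols |>
    dplyr::mutate(stays_total = c(1L, 1L, 0L, 0L), stays_cvd = c(1L, 1L, 0L, 0L),
                  stays_chd = c(1L, 1L, 0L, 0L),
                  los_total = c(3L, 5L, 0L, 0L), los_cvd = c(3L, 5L, 0L, 0L),
                  los_chd = c(3L, 5L, 0L, 0L),
                  consultations = 0L, pci = c(1L, 0L, 0L, 0L), cabg = 0L)
  u1 <- summarize_utilization(busy, windows, "first_scad_year")
  val <- function(m) u1$value[u1$measure == m]
  expect_equal(val("hospitalized_chd_pct"), 100)
  expect_equal(val("stays_chd_mean_hospitalized"), 2)
  expect_equal(val("los_chd_per_stay_hospitalized"), 4)
  expect_equal(val("revascularized_pct"), 100)
  expect_equal(val("pci_pct"), 100)
  expect_equal(val("cabg_pct"), 0)
})

test_that("conditional utilization means equal a filtered-subset oracle", {
  cfg <- quick_config(n = 600, seed = 47)
  cohort <- simulate_scad_cohort(cfg)
  w <- build_analysis_windows(cohort$baseline, cohort$events, cfg$horizon_cycles)
  u <- summarize_utilization(cohort$panel, w, "first_scad_year")

  keep <- w$patient_id[w$window_kind == "first_scad_year" & w$complete]
  sub <- cohort$panel[cohort$panel$patient_id %in% keep & cohort$panel$cycle <= 4, ]
  stays <- tapply(sub$stays_chd, sub$patient_id, sum)
  los <- tapply(sub$los_chd, sub$patient_id, sum)
  stays <- stays[match(keep, names(stays))]; stays[is.na(stays)] <- 0
  los <- los[match(keep, names(los))]; los[is.na(los)] <- 0
  hosp <- stays > 0
  expect_equal(u$value[u$measure == "hospitalized_chd_pct"], 100 * mean(hosp))
  expect_equal(u$value[u$measure == "stays_chd_mean_hospitalized"],
               mean(stays[hosp]))
  expect_equal(u$value[u$measure == "los_chd_per_stay_hospitalized"],
               mean(los[hosp] / stays[hosp]))
})
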