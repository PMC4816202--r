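test_that("generator output is deterministic given config and seed", {
  cfg <- quick_config(n = 300, seed = 42)
  a <- simulate_scad_cohort(cfg)
  b <- simulate_scad_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$events, b$events)
  expect_identical(a$panel, b$panel)
})

test_that("baseline covariate mix matches the configured cohort structure", {
  cfg <- quick_config(n = 100000, seed = 1)
  b <- generate_baseline(cfg)
  expect_equal(nrow(b), 100000)
  expect_lt(abs(mean(b$sex == "female") - 0.44), 0.005)
  expect_lt(abs(mean(b$diagnosis == "stable_angina") - 0.474), 0.005)
})

test_that("degenerate configuration yields a single fully observed male row", {
  cfg <- quick_config(n = 1, seed = 9, female_fraction = 0,
                      missingness_rates = c(heart_rate = 0, creatinine = 0))
  b <- generate_baseline(cfg)
  expect_equal(nrow(b), 1)
  expect_identical(b$sex, "male")
  expect_false(anyNA(b))
})

test_that("biomarker missingness matches its binomial rate", {
  n <- 50000
  cfg <- quick_config(n = n, seed = 7,
                      missingness_rates = c(heart_rate = 0.3, creatinine = 0))
  b <- generate_baseline(cfg)
  obs_frac <- mean(is.na(b$heart_rate))
  # independent binomial oracle: 3 SEs around the configured rate
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(obs_frac - 0.3), max(3 * se, 0.01))
  expect_false(anyNA(b$creatinine))
})

test_that("null hazard process produces no events", {
  cfg <- quick_config(n = 200, seed = 3, hazard_params = hp_flat(),
                      censoring_rate = 0)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  expect_equal(nrow(ev), 0)
})

test_that("single-risk survival follows the geometric closed form", {
  n <- 50000
  h <- 0.02
  cfg <- quick_config(n = n, seed = 11, hazard_params = hp_flat(cvdd = h),
                      censoring_rate = 0, horizon_cycles = 20)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  exits <- patient_exits(b, ev, cfg$horizon_cycles)
  km <- survival::survfit(
    survival::Surv(exits$exit_cycle, exits$exit_reason == "death_cvd") ~ 1
  )
  s20 <- summary(km, times = 20)$surv
  q <- 1 - exp(-h)  # per-cycle death probability of the discrete process
  s_true <- (1 - q)^20
  se <- sqrt(s_true * (1 - s_true) / n)
  expect_lt(abs(s20 - s_true), 3 * se)
  expect_lt(abs(s20 - (1 - h)^20), 0.01)
})

test_that("event-type split converges to the hazard ratio", {
  n <- 50000
  cfg <- quick_config(n = n, seed = 13,
                      hazard_params = hp_flat(ami = 0.01, cvdd = 0.02),
                      censoring_rate = 0, horizon_cycles = 10)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  first <- ev |> dplyr::group_by(patient_id) |>
    dplyr::slice_min(cycle, n = 1, with_ties = FALSE) |> dplyr::ungroup()
  frac_ami <- mean(first$event == "ami")
  se <- sqrt((1 / 3) * (2 / 3) / nrow(first))
  expect_lt(abs(frac_ami - 1 / 3), 3 * se)
})

test_that("deaths after a non-fatal event occur strictly later", {
  cfg <- quick_config(n = 5000, seed = 17,
                      hazard_params = hp_flat(ami = 0.03, post_cvd = 0.1,
                                              post_ncvd = 0.02),
                      horizon_cycles = 30)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  amis <- ev |> dplyr::filter(event == "ami")
  deaths <- ev |> dplyr::filter(event %in% c("cvd_death", "noncvd_death"))
  joined <- dplyr::inner_join(amis, deaths, by = "patient_id",
                              suffix = c("_ami", "_death"))
  expect_gt(nrow(joined), 0)
  expect_true(all(joined$cycle_death > joined$cycle_ami))
  # at most one first event, and only deaths may follow it
  per <- ev |> dplyr::filter(event != "censored") |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(
      n_nonfatal = sum(event %in% c("ami", "ischaemic_stroke",
                                    "haemorrhagic_stroke")),
      n_death = sum(event %in% c("cvd_death", "noncvd_death"))
    )
  expect_true(all(per$n_nonfatal <= 1))
  expect_true(all(per$n_death <= 1))
})

test_that("vanishing gamma noise pins period costs to the configured mean", {
  cfg <- quick_config(n = 50, seed = 5, hazard_params = hp_flat(),
                      cost_params = flat_cost_params(trend = c(total = 0, cvd = 0,
                                                               chd = 0)),
                      gamma_shape = 1e6, censoring_rate = 0, horizon_cycles = 8)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  panel <- simulate_costs(b, ev, cfg)
  totals <- compose_cost_categories(panel)$total_cost
  expect_true(all(abs(totals - 341) / 341 < 0.01))
})

test_that("cycle-1 cost mean matches the 90-day baseline parameter", {
  n <- 20000
  cfg <- quick_config(n = n, seed = 19, hazard_params = hp_flat(),
                      cost_params = flat_cost_params(),
                      censoring_rate = 0, horizon_cycles = 4)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  panel <- simulate_costs(b, ev, cfg)
  cyc1 <- compose_cost_categories(panel |> dplyr::filter(cycle == 1))$total_cost
  se <- stats::sd(cyc1) / sqrt(n)
  expect_lt(abs(mean(cyc1) - 341), 3 * se)
  # per-cycle means follow the additive trend
  comp <- compose_cost_categories(panel)
  by_cycle <- comp |> dplyr::group_by(cycle) |>
    dplyr::summarise(m = mean(total_cost), se = stats::sd(total_cost) / sqrt(dplyr::n()))
  expect_true(all(abs(by_cycle$m - (341 + 10 * (by_cycle$cycle - 1))) <
                    3 * by_cycle$se))
})

test_that("censoring truncates the cost panel at the censoring cycle", {
  cfg <- quick_config(n = 2000, seed = 23, hazard_params = hp_flat(),
                      censoring_rate = 0.1, horizon_cycles = 12)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  panel <- simulate_costs(b, ev, cfg)
  cens <- ev |> dplyr::filter(event == "censored")
  expect_gt(nrow(cens), 0)
  last <- panel |> dplyr::group_by(patient_id) |>
    dplyr::summarise(last_cycle = max(cycle))
  joined <- dplyr::inner_join(cens, last, by = "patient_id")
  expect_true(all(joined$last_cycle == joined$cycle))
})

test_that("cost components respect the category nesting row by row", {
  cfg <- quick_config(n = 500, seed = 29)
  cohort <- simulate_scad_cohort(cfg)
  p <- cohort$panel
  expect_true(all(p$inpatient_chd <= p$inpatient_cvd + 1e-9))
  expect_true(all(p$inpatient_cvd <= p$inpatient_total + 1e-9))
  expect_true(all(p$drugs_cvd <= p$drugs_total + 1e-9))
  expect_true(all(p$inpatient_total >= 0))
})

test_that("cost parameters implying negative component means are rejected", {
  bad <- flat_cost_params()
  bad$chd <- panel_cost_params("chd", baseline = 100)  # below shared components
  cfg <- quick_config(n = 50, seed = 31, hazard_params = hp_flat(),
                      cost_params = bad)
  b <- generate_baseline(cfg)
  ev <- simulate_events(b, cfg)
  expect_error(simulate_costs(b, ev, cfg), class = "scadcost_config_error")
})
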