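test_that("design panel bands time since event correctly", {
  b <- mini_baseline(3)
  ev <- tibble::tibble(
    patient_id = c(1L, 3L),
    event = c("ami", "noncvd_death"),
    cycle = c(6L, 3L)
  )
  panel <- tidyr::expand_grid(patient_id = 1:3, cycle = 1:12) |>
    dplyr::filter(!(patient_id == 3 & cycle > 3)) |>
    dplyr::mutate(inpatient_total = 100, inpatient_cvd = 50, inpatient_chd = 25,
                  primary_care = 20, diagnostics = 5, drugs_total = 10,
                  drugs_cvd = 4)
  d <- build_design_panel(panel, ev, b)

  p1 <- d[d$patient_id == 1, ]
  expect_equal(p1$ami_band1, as.integer(p1$cycle == 6))
  expect_equal(p1$ami_band2, as.integer(p1$cycle == 7))
  expect_equal(p1$ami_band3, as.integer(p1$cycle == 8))
  expect_equal(p1$ami_band4, as.integer(p1$cycle == 9))
  expect_equal(p1$ami_long, as.integer(p1$cycle >= 10))
  # bands mutually exclusive
  expect_true(all(p1$ami_band1 + p1$ami_band2 + p1$ami_band3 + p1$ami_band4 +
                    p1$ami_long <= 1))

  p2 <- d[d$patient_id == 2, ]
  ev_cols <- grep("_band|_long|death_", names(d), value = TRUE)
  expect_true(all(as.matrix(p2[ev_cols]) == 0))

  p3 <- d[d$patient_id == 3, ]
  expect_equal(max(p3$cycle), 3)
  expect_equal(p3$death_noncvd, as.integer(p3$cycle == 3))

  dup <- dplyr::bind_rows(panel, panel[1, ])
  expect_error(build_design_panel(dup, ev, b), class = "scadcost_data_error")
})

test_that("a noise-free panel is recovered exactly", {
  truth <- flat_cost_params(with_events = TRUE, death_increments = TRUE)
  cfg <- quick_config(n = 800, seed = 53,
                      hazard_params = hp_flat(ami = 0.02, is = 0.01, hs = 0.004,
                                              cvdd = 0.008, ncvdd = 0.012),
                      cost_params = truth, gamma_shape = Inf,
                      censoring_rate = 0.01, horizon_cycles = 24)
  cohort <- simulate_scad_cohort(cfg)
  d <- build_design_panel(cohort$panel, cohort$events, cohort$baseline)
  for (cat in c("total", "cvd", "chd")) {
    fit <- fit_panel(d, cat)
    expect_equal(fit$params$baseline, truth[[cat]]$baseline, tolerance = 1e-6)
    expect_equal(fit$params$trend, truth[[cat]]$trend, tolerance = 1e-6)
    expect_equal(fit$params$event_increments$ami$bands,
                 truth[[cat]]$event_increments$ami$bands, tolerance = 1e-6)
    expect_equal(fit$params$event_increments$ami$long_run,
                 truth[[cat]]$event_increments$ami$long_run, tolerance = 1e-6)
    expect_equal(unname(fit$params$death_increments),
                 unname(truth[[cat]]$death_increments), tolerance = 1e-6)
  }
})

test_that("panel estimates are invariant to row permutation", {
  cfg <- quick_config(n = 300, seed = 59,
                      hazard_params = hp_flat(ami = 0.02, cvdd = 0.01,
                                              ncvdd = 0.01),
                      cost_params = flat_cost_params(with_events = TRUE,
                                                     death_increments = TRUE),
                      horizon_cycles = 16)
  cohort <- simulate_scad_cohort(cfg)
  d <- build_design_panel(cohort$panel, cohort$events, cohort$baseline)
  f1 <- fit_panel(d, "total")
  set.seed(2)
  f2 <- fit_panel(d[sample(nrow(d)), ], "total")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("period cost prediction follows the additive structure", {
  p <- panel_cost_params(
    baseline = 341, trend = 10,
    event_increments = list(ami = list(bands = c(5028, 1500, 1000, 700),
                                       long_run = 521)),
    death_increments = c(cvd_death = 2008, noncvd_death = 2240)
  )
  expect_equal(predict_period_cost(p, cycle = 1), 341)
  expect_equal(predict_period_cost(p, cycle = 2), 351)
  expect_equal(predict_period_cost(p, cycle = 20, event = "ami",
                                   cycles_since = 6), 341 + 10 * 19 + 521)
  expect_equal(predict_period_cost(p, cycle = 6, event = "ami",
                                   cycles_since = 0), 341 + 50 + 5028)
  expect_equal(predict_period_cost(p, cycle = 3, death = "cvd_death"),
               341 + 20 + 2008)
  expect_error(predict_period_cost(p, cycle = 1, event = "appendicitis",
                                   cycles_since = 0),
               class = "scadcost_data_error")
  expect_error(predict_period_cost(p, cycle = 1, death = "sudden"),
               class = "scadcost_data_error")

  neg <- panel_cost_params(baseline = 10, trend = -20)
  expect_warning(v <- predict_period_cost(neg, cycle = 5), "floored")
  expect_equal(v, 0)

  # covariate effects require a covering profile
  pc <- panel_cost_params(baseline = 100,
                          covariate_effects = c(sex_female = -30))
  expect_equal(predict_period_cost(pc, profile = list(sex_female = 1), cycle = 1),
               70)
  expect_error(predict_period_cost(pc, profile = list(), cycle = 1),
               class = "scadcost_data_error")
})

test_that("one-year event cost is the sum of the four bands", {
  p <- panel_cost_params(
    baseline = 341,
    event_increments = list(ami = list(bands = c(5028, 1500, 1000, 700),
                                       long_run = 521))
  )
  expect_equal(event_year_cost(p, "ami"), 5028 + 1500 + 1000 + 700)
  expect_error(event_year_cost(p, "ischaemic_stroke"),
               class = "scadcost_data_error")
})

test_that("fitted category triplet predicts chd <= cvd <= total", {
  cfg <- quick_config(n = 1500, seed = 61,
                      hazard_params = hp_flat(ami = 0.015, is = 0.008,
                                              hs = 0.003, cvdd = 0.006,
                                              ncvdd = 0.01),
                      cost_params = flat_cost_params(with_events = TRUE,
                                                     death_increments = TRUE),
                      horizon_cycles = 24)
  cohort <- simulate_scad_cohort(cfg)
  d <- build_design_panel(cohort$panel, cohort$events, cohort$baseline)
  fits <- lapply(c(total = "total", cvd = "cvd", chd = "chd"),
                 function(cat) fit_panel(d, cat))
  states <- list(list(), list(event = "ami", cycles_since = 0),
                 list(event = "ami", cycles_since = 2),
                 list(event = "ami", cycles_since = 8),
                 list(event = "ischaemic_stroke", cycles_since = 1),
                 list(death = "cvd_death"), list(death = "noncvd_death"))
  for (cyc in c(1, 10, 20)) {
    for (st in states) {
      args <- c(list(cycle = cyc), st)
      v <- vapply(fits, function(f) {
        do.call(predict_period_cost, c(list(params = f$params), args))
      }, numeric(1))
      expect_true(v[["chd"]] <= v[["cvd"]] + 1e-6 &&
                    v[["cvd"]] <= v[["total"]] + 1e-6)
    }
  }
})
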