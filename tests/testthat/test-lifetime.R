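flat_profile <- list(age10c = 0, sex_female = 0)

test_that("a hazard-free trace reproduces the additive cost ramp exactly", {
  cp <- flat_cost_params()
  tr <- run_trace(tp_flat(), flat_profile, horizon_cycles = 30, cost_params = cp)
  expect_equal(tr$costs$total, 341 + 10 * (0:29), tolerance = 1e-12)
  expect_equal(tr$costs$chd, 240 + 7 * (0:29), tolerance = 1e-12)
  expect_equal(tr$survival, rep(1, 30))
})

test_that("trace occupancy rows always sum to one", {
  tp <- tp_flat(ami = 0.01, is = 0.004, hs = 0.002, cvdd = 0.006, ncvdd = 0.012)
  tr <- run_trace(tp, flat_profile, horizon_cycles = 200)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
  dead <- rowSums(tr$occupancy[, c("cvd_death", "noncvd_death")])
  expect_true(all(diff(dead) >= -1e-12))        # absorbing states grow
  expect_true(all(diff(tr$survival) <= 1e-12))  # survival non-increasing
  expect_true(all(tr$survival >= 0 & tr$survival <= 1))
})

test_that("discounting matches the annuity closed form", {
  expect_equal(discount_stream(c(100, 200, 300), 0), 600)
  r <- 0.035
  n <- 80
  rho <- (1 + r)^(-90 / 365.25)
  expect_equal(discount_stream(rep(100, n), r, timing = "mid"),
               100 * rho^0.5 * (1 - rho^n) / (1 - rho), tolerance = 1e-9)
  expect_equal(discount_stream(rep(100, n), r, timing = "end"),
               100 * rho * (1 - rho^n) / (1 - rho), tolerance = 1e-9)
  # a single cost one year out discounts by exactly one year's growth
  k <- 365.25 / 90 + 0.5  # mid-cycle time of 1 year, in cycles
  expect_equal(1035 * (1 + r)^(-(k - 0.5) * 90 / 365.25), 1000, tolerance = 1e-9)
  expect_error(discount_stream(1:3, -0.01), class = "scadcost_argument_error")
})

test_that("projection composes trivially under zero hazards", {
  cp <- flat_cost_params(trend = c(total = 0, cvd = 0, chd = 0))
  cp$total$baseline <- 100; cp$cvd$baseline <- 100; cp$chd$baseline <- 100
  pr <- suppressWarnings(project(tp_flat(), flat_profile, cost_params = cp,
                                 horizon_cycles = 20, rate = 0))
  expect_equal(pr$five_year$undiscounted,
               pr$five_year$discounted)  # rate 0: discounted = undiscounted
  expect_equal(pr$five_year$undiscounted[pr$five_year$category == "total"], 2000)
  expect_error(project(tp_flat(), flat_profile, cost_params = cp,
                       horizon_cycles = 19), class = "scadcost_argument_error")
  expect_error(project(tp_flat(), flat_profile, cost_params = cp[c("total", "cvd")],
                       horizon_cycles = 20), class = "scadcost_argument_error")
})

test_that("immediate death accrues one period cost plus the death increment", {
  cp <- flat_cost_params(trend = c(total = 0, cvd = 0, chd = 0),
                         death_increments = TRUE)
  pr <- project(tp_flat(cvdd = 50), flat_profile, cost_params = cp,
                horizon_cycles = 40, rate = 0)
  expect_equal(pr$lifetime$undiscounted[pr$lifetime$category == "total"],
               341 + 2008, tolerance = 1e-6)
  expect_equal(pr$life_expectancy, 0, tolerance = 1e-6)
})

test_that("discounting never increases a cost cell", {
  tp <- tp_flat(ami = 0.01, cvdd = 0.005, ncvdd = 0.02)
  cp <- flat_cost_params(with_events = TRUE, death_increments = TRUE)
  pr <- project(tp, flat_profile, cost_params = cp, horizon_cycles = 400,
                rate = 0.035)
  for (tab in list(pr$five_year, pr$lifetime)) {
    expect_true(all(tab$discounted <= tab$undiscounted + 1e-9))
  }
  # category nesting and horizon ordering
  for (tab in list(pr$five_year, pr$lifetime)) {
    v <- setNames(tab$undiscounted, tab$category)
    expect_true(v[["chd"]] <= v[["cvd"]] && v[["cvd"]] <= v[["total"]])
  }
  expect_true(all(pr$lifetime$undiscounted >= pr$five_year$undiscounted))
  td <- tidy(pr)
  expect_equal(nrow(td), 12)
})

test_that("lifetime totals are non-decreasing in the horizon", {
  tp <- tp_flat(ami = 0.01, cvdd = 0.01, ncvdd = 0.02)
  cp <- flat_cost_params(with_events = TRUE)
  pr1 <- suppressWarnings(project(tp, flat_profile, cost_params = cp,
                                  horizon_cycles = 100))
  pr2 <- suppressWarnings(project(tp, flat_profile, cost_params = cp,
                                  horizon_cycles = 250))
  expect_true(all(pr2$lifetime$undiscounted >= pr1$lifetime$undiscounted - 1e-9))
})

test_that("microsimulation agrees with the deterministic trace", {
  tp <- tp_flat(ami = 0.012, is = 0.005, hs = 0.002, cvdd = 0.008,
                ncvdd = 0.015)
  cp <- flat_cost_params(with_events = TRUE, death_increments = TRUE)
  pr <- suppressWarnings(project(tp, flat_profile, cost_params = cp,
                                 horizon_cycles = 60, rate = 0.035))
  ms <- microsimulate(tp, cp, flat_profile, n = 20000, seed = 101,
                      horizon_cycles = 60, rate = 0.035)
  for (cat in c("total", "cvd", "chd")) {
    tr_cell <- pr$lifetime$undiscounted[pr$lifetime$category == cat]
    ms_row <- ms$lifetime[ms$lifetime$category == cat, ]
    expect_lt(abs(tr_cell - ms_row$undiscounted), 3 * ms_row$se_undiscounted)
  }
  expect_lt(abs(pr$five_year_risk - ms$five_year_risk),
            3 * ms$five_year_risk_se)
  expect_lt(abs(pr$life_expectancy - ms$life_expectancy),
            3 * ms$life_expectancy_se)
  # determinism and the n >= 1000 precondition
  ms2 <- microsimulate(tp, cp, flat_profile, n = 20000, seed = 101,
                       horizon_cycles = 60, rate = 0.035)
  expect_identical(ms$lifetime, ms2$lifetime)
  expect_error(microsimulate(tp, cp, flat_profile, n = 10),
               class = "scadcost_argument_error")
})

test_that("Monte Carlo errors shrink like one over root n", {
  tp <- tp_flat(ami = 0.01, cvdd = 0.01, ncvdd = 0.02)
  cp <- flat_cost_params(with_events = TRUE)
  ms1 <- microsimulate(tp, cp, flat_profile, n = 4000, seed = 5,
                       horizon_cycles = 40)
  ms2 <- microsimulate(tp, cp, flat_profile, n = 16000, seed = 5,
                       horizon_cycles = 40)
  ratio <- ms1$lifetime$se_undiscounted[1] / ms2$lifetime$se_undiscounted[1]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.6)

  # zero hazards: no variance in occupancy
  ms0 <- microsimulate(tp_flat(), cp, flat_profile, n = 1000, seed = 5,
                       horizon_cycles = 25)
  expect_equal(ms0$five_year_risk_se, 0)
  expect_true(all(ms0$occupancy[, "stable"] == 1))
})

test_that("high-risk profiles cost more early but less over a lifetime", {
  cp <- flat_cost_params(with_events = TRUE, death_increments = TRUE)
  high <- tp_flat(ami = 0.05, is = 0.01, hs = 0.004, cvdd = 0.03, ncvdd = 0.05)
  low <- tp_flat(ami = 0.004, is = 0.001, hs = 0.0004, cvdd = 0.002,
                 ncvdd = 0.004)
  pr_high <- suppressWarnings(project(high, flat_profile, cost_params = cp,
                                      horizon_cycles = 400, rate = 0))
  pr_low <- suppressWarnings(project(low, flat_profile, cost_params = cp,
                                     horizon_cycles = 400, rate = 0))
  cum_high <- cumsum(pr_high$cost_streams$total)
  cum_low <- cumsum(pr_low$cost_streams$total)
  expect_gt(cum_high[4], cum_low[4])    # event increments dominate early
  expect_gt(pr_low$lifetime$undiscounted[1],
            pr_high$lifetime$undiscounted[1])  # longevity dominates later
  expect_gt(pr_low$life_expectancy, pr_high$life_expectancy)
})
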