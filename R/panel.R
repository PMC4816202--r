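# 90-day panel cost model: additive GBP-scale mean structure (baseline,
# per-cycle trend, covariate effects, time-since-event band increments,
# death-cycle increments) estimated by pooled least squares with
# patient-clustered uncertainty.

#' Build the patient-cycle design panel
#'
#' Expands the period-cost panel into the regression design: one row per
#' patient-cycle with the elapsed-cycle index, time-invariant covariates,
#' mutually exclusive indicators for each non-fatal event type in four
#' 90-day bands (band 1 = the event cycle) then a long-run indicator from
#' the fifth post-event cycle, indicators for the cycle of CVD / non-CVD
#' death, and the composed total/CVD/CHD cost categories as responses.
#'
#' @param panel Period-cost tibble.
#' @param events Event tibble.
#' @param baseline Baseline tibble.
#' @param covariates Character vector of design-covariate columns to carry
#'   (default none; see [design_covariates()]).
#' @return A design tibble, one row per patient-cycle.
#' @export
build_design_panel <- function(panel, events, baseline, covariates = character()) {
  if (anyDuplicated(panel[c("patient_id", "cycle")])) {
    dup <- panel[duplicated(panel[c("patient_id", "cycle")]), ]
    stop_data(paste0("duplicate patient-cycle rows, e.g. patient ",
                     dup$patient_id[1], " cycle ", dup$cycle[1]))
  }
  design <- compose_cost_categories(panel)
  fe <- first_nonfatal(events)
  deaths <- events |>
    dplyr::filter(.data$event %in% DEATH_EVENTS) |>
    dplyr::transmute(patient_id = .data$patient_id, death_event = .data$event,
                     death_cycle = .data$cycle)
  design <- design |>
    dplyr::left_join(fe, by = "patient_id") |>
    dplyr::left_join(deaths, by = "patient_id") |>
    dplyr::mutate(
      elapsed = .data$cycle - 1L,
      cycles_since = ifelse(!is.na(.data$event_cycle) & .data$cycle >= .data$event_cycle,
                            .data$cycle - .data$event_cycle, NA_integer_)
    )
  for (ev in NONFATAL_EVENTS) {
    in_ev <- !is.na(design$cycles_since) & design$event_type == ev
    for (b in 1:4) {
      design[[paste0(ev, "_band", b)]] <-
        as.integer(in_ev & design$cycles_since == b - 1L)
    }
    design[[paste0(ev, "_long")]] <- as.integer(in_ev & design$cycles_since >= 4L)
  }
  design$death_cvd <- as.integer(!is.na(design$death_cycle) &
                                   design$cycle == design$death_cycle &
                                   design$death_event == "cvd_death")
  design$death_noncvd <- as.integer(!is.na(design$death_cycle) &
                                      design$cycle == design$death_cycle &
                                      design$death_event == "noncvd_death")
  if (length(covariates)) {
    dc <- design_covariates(baseline)
    miss <- setdiff(covariates, names(dc))
    if (length(miss)) {
      stop_data(paste0("unknown covariate column(s): ", paste(miss, collapse = ", ")))
    }
    dc <- dc[covariates]
    dc$patient_id <- baseline$patient_id
    design <- dplyr::left_join(design, dc, by = "patient_id")
  }
  design |>
    dplyr::select(-dplyr::all_of(c("event_type", "event_cycle", "death_event",
                                   "death_cycle")))
}

#' Fit the 90-day panel cost model
#'
#' Pooled least squares of one cost category on the additive design from
#' [build_design_panel()], with cluster-robust (patient-level) standard
#' errors. The fitted coefficients are returned both as a coefficient table
#' and mapped into a [panel_cost_params()] object usable for prediction and
#' projection.
#'
#' @param design Design tibble from [build_design_panel()].
#' @param category `"total"`, `"cvd"`, or `"chd"`.
#' @param covariates Covariate columns included in the mean structure (must
#'   be present in `design`).
#' @return An object of class `panel_cost_fit` with elements `params`
#'   (a `panel_cost_params`), `coefficients`, `se` (cluster-robust), `vcov`,
#'   `n_obs`, `n_patients`, `category`.
#' @export
fit_panel <- function(design, category = "total", covariates = character()) {
  category <- match.arg(category, COST_CATEGORIES)
  response <- paste0(category, "_cost")
  event_cols <- unlist(lapply(NONFATAL_EVENTS, function(ev) {
    cols <- c(paste0(ev, "_band", 1:4), paste0(ev, "_long"))
    cols[vapply(cols, function(cl) any(design[[cl]] > 0), logical(1))]
  }))
  death_cols <- c("death_cvd", "death_noncvd")
  death_cols <- death_cols[vapply(death_cols, function(cl) any(design[[cl]] > 0),
                                  logical(1))]
  rhs <- c("elapsed", covariates, event_cols, death_cols)
  form <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = design)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("collinear panel design; aliased columns: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "scadcost_singular_error")
  }
  vc <- sandwich::vcovCL(fit, cluster = design$patient_id)
  se <- sqrt(diag(vc))

  inc <- list()
  for (ev in NONFATAL_EVENTS) {
    cols <- c(paste0(ev, "_band", 1:4), paste0(ev, "_long"))
    if (any(cols %in% names(cf))) {
      vals <- setNames(rep(0, 5), cols)
      vals[intersect(cols, names(cf))] <- cf[intersect(cols, names(cf))]
      inc[[ev]] <- list(bands = unname(vals[1:4]), long_run = unname(vals[5]))
    }
  }
  di <- c(cvd_death = unname(cf["death_cvd"]), noncvd_death = unname(cf["death_noncvd"]))
  di[is.na(di)] <- 0
  params <- panel_cost_params(
    category = category,
    baseline = unname(cf["(Intercept)"]),
    trend = unname(cf["elapsed"]),
    covariate_effects = cf[intersect(covariates, names(cf))],
    event_increments = inc,
    death_increments = di
  )
  structure(
    list(
      params = params,
      coefficients = cf,
      se = se,
      vcov = vc,
      n_obs = nrow(design),
      n_patients = dplyr::n_distinct(design$patient_id),
      category = category,
      formula = form
    ),
    class = "panel_cost_fit"
  )
}

#' @rdname fit_panel
#' @param x A `panel_cost_fit`.
#' @param ... Unused.
#' @method tidy panel_cost_fit
#' @export
tidy.panel_cost_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se[names(x$coefficients)])
  )
}

#' @rdname fit_panel
#' @method glance panel_cost_fit
#' @export
glance.panel_cost_fit <- function(x, ...) {
  tibble::tibble(category = x$category, n_obs = x$n_obs,
                 n_patients = x$n_patients,
                 nterms = length(x$coefficients))
}

#' @export
print.panel_cost_fit <- function(x, ...) {
  cat(sprintf("<panel_cost_fit: %s costs, %d patient-cycles, %d patients>\n",
              x$category, x$n_obs, x$n_patients))
  print(x$params)
  invisible(x)
}

#' Predict one 90-day period cost
#'
#' Evaluates the additive mean: baseline + trend x (cycle - 1) + covariate
#' effects + the time-since-event band or long-run increment + the
#' death-cycle increment. Negative predictions are floored at zero with a
#' warning.
#'
#' @param params A [panel_cost_params()].
#' @param profile Named list/vector of covariate values covering
#'   `params$covariate_effects` (may be empty when the params carry no
#'   covariate effects).
#' @param cycle Elapsed model cycle (1-based).
#' @param event Non-fatal event type earlier in follow-up, or `NULL`.
#' @param cycles_since Cycles since that event (0 = the event cycle; 0-3
#'   map to bands 1-4, 4+ to the long-run increment).
#' @param death `"cvd_death"`, `"noncvd_death"`, or `NULL`: death occurring
#'   in this cycle.
#' @return Expected cost (GBP) for the period.
#' @export
#' @examples
#' p <- panel_cost_params(
#'   baseline = 341, trend = 10,
#'   event_increments = list(ami = list(bands = c(5028, 1500, 1000, 700),
#'                                      long_run = 521))
#' )
#' predict_period_cost(p, cycle = 1)                       # 341
#' predict_period_cost(p, cycle = 20, event = "ami", cycles_since = 6) # 1052
predict_period_cost <- function(params, profile = NULL, cycle = 1,
                                event = NULL, cycles_since = NULL, death = NULL) {
  stopifnot(inherits(params, "panel_cost_params"))
  m <- params$baseline + params$trend * (cycle - 1)
  if (length(params$covariate_effects)) {
    miss <- setdiff(names(params$covariate_effects), names(profile))
    if (length(miss)) {
      stop_data(paste0("profile missing covariate(s): ", paste(miss, collapse = ", ")))
    }
    m <- m + sum(params$covariate_effects *
                   unlist(profile[names(params$covariate_effects)]))
  }
  if (!is.null(event)) {
    inc <- params$event_increments[[event]]
    if (is.null(inc)) stop_data(paste0("unknown event type: ", event))
    if (is.null(cycles_since) || cycles_since < 0) {
      stop_data("`cycles_since` must be a nonnegative integer when `event` is set")
    }
    m <- m + if (cycles_since <= 3) inc$bands[cycles_since + 1] else inc$long_run
  }
  if (!is.null(death)) {
    if (!death %in% DEATH_EVENTS) stop_data(paste0("unknown death type: ", death))
    m <- m + params$death_increments[[death]]
  }
  if (m < 0) {
    warn(sprintf("predicted period cost %.2f floored at 0", m))
    m <- 0
  }
  unname(m)
}

#' One-year incremental cost of a non-fatal event
#'
#' The sum of the four 90-day band increments: the total extra cost in the
#' 360 days starting with the event cycle, ignoring mortality risk.
#'
#' @param params A [panel_cost_params()].
#' @param event Event type.
#' @return GBP increment.
#' @export
event_year_cost <- function(params, event) {
  inc <- params$event_increments[[event]]
  if (is.null(inc)) stop_data(paste0("unknown event type: ", event))
  sum(inc$bands)
}
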