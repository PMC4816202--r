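# Lifetime cost projection: deterministic cohort trace over the Markov
# structure combined with the panel cost parameters, discounting, and a
# microsimulation oracle for validation.

# Per-category helpers: additive covariate effect for a profile, and the
# state-specific increments (0 for stable, band/long-run for tunnels).
profile_cost_effect <- function(cp, profile) {
  if (!length(cp$covariate_effects)) return(0)
  miss <- setdiff(names(cp$covariate_effects), names(profile))
  if (length(miss)) {
    stop_data(paste0("profile missing covariate(s): ", paste(miss, collapse = ", ")))
  }
  sum(cp$covariate_effects * unlist(profile[names(cp$covariate_effects)]))
}

state_increments <- function(cp) {
  states <- scad_states()
  inc <- setNames(rep(0, length(states)), states)
  for (ev in NONFATAL_EVENTS) {
    e <- cp$event_increments[[ev]]
    if (is.null(e)) next
    inc[paste0(ev, "_b", 1:4)] <- e$bands
    inc[paste0(ev, "_long")] <- e$long_run
  }
  inc
}

# Resolve a cost-params argument: accepts panel_cost_params or a
# panel_cost_fit and checks the category triplet when needed.
resolve_cost_params <- function(cost_params) {
  get1 <- function(x) if (inherits(x, "panel_cost_fit")) x$params else x
  miss <- setdiff(COST_CATEGORIES, names(cost_params))
  if (length(miss)) {
    abort(paste0("`cost_params` missing category: ", paste(miss, collapse = ", ")),
          class = "scadcost_argument_error")
  }
  out <- lapply(cost_params[COST_CATEGORIES], get1)
  for (cp in out) {
    if (!inherits(cp, "panel_cost_params")) {
      abort("`cost_params` elements must be panel_cost_params or panel_cost_fit",
            class = "scadcost_argument_error")
    }
  }
  out
}

#' Run the deterministic cohort trace
#'
#' Propagates state-occupancy probabilities cycle by cycle from unit mass
#' on the stable state, and (when cost parameters are supplied) accumulates
#' the expected per-cycle cost of each category: every alive state accrues
#' the additive period cost of its band; the probability mass dying in a
#' cycle accrues that cycle's background cost plus the death-cycle
#' increment.
#'
#' @param params A `transition_params` (or coercible).
#' @param profile Named covariate values.
#' @param horizon_cycles Number of cycles to propagate.
#' @param cost_params Optional named list (`total`, `cvd`, `chd`) of
#'   [panel_cost_params()] (or [fit_panel()] results).
#' @return An object of class `cohort_trace`: `occupancy` (cycles x states
#'   matrix; row 0 is the starting vector), `survival` (per-cycle
#'   probability of being alive at cycle end), `costs` (tibble of expected
#'   per-cycle GBP by category, or `NULL`).
#' @export
run_trace <- function(params, profile, horizon_cycles, cost_params = NULL) {
  if (horizon_cycles < 1) {
    abort("`horizon_cycles` must be at least 1", class = "scadcost_argument_error")
  }
  params <- as_transition_params(params)
  states <- scad_states()
  P <- transition_matrix(params, profile)
  occ <- matrix(0, horizon_cycles + 1L, length(states),
                dimnames = list(0:horizon_cycles, states))
  occ[1, "stable"] <- 1
  for (t in seq_len(horizon_cycles)) {
    occ[t + 1L, ] <- occ[t, ] %*% P
  }
  dead <- occ[-1, DEATH_EVENTS, drop = FALSE]
  survival <- unname(1 - rowSums(dead))

  costs <- NULL
  if (!is.null(cost_params)) {
    cost_params <- resolve_cost_params(cost_params)
    alive_states <- setdiff(states, DEATH_EVENTS)
    d_enter <- dead - occ[-nrow(occ), DEATH_EVENTS, drop = FALSE]
    cycles <- seq_len(horizon_cycles)
    costs <- tibble::tibble(cycle = cycles)
    for (cat in COST_CATEGORIES) {
      cp <- cost_params[[cat]]
      ce <- profile_cost_effect(cp, profile)
      base_t <- cp$baseline + cp$trend * (cycles - 1) + ce
      inc <- state_increments(cp)[alive_states]
      alive_occ <- occ[-1, alive_states, drop = FALSE]
      costs[[cat]] <- unname(
        (rowSums(alive_occ) + rowSums(d_enter)) * base_t +
        drop(alive_occ %*% inc) +
        d_enter[, "cvd_death"] * cp$death_increments[["cvd_death"]] +
        d_enter[, "noncvd_death"] * cp$death_increments[["noncvd_death"]])
    }
  }
  structure(
    list(occupancy = occ, survival = survival, costs = costs,
         profile = profile, horizon_cycles = horizon_cycles),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace: %d cycles, survival at horizon %.4f>\n",
              x$horizon_cycles, x$survival[length(x$survival)]))
  invisible(x)
}

#' Survival and expected-cost curves from a trace
#'
#' @param object A `cohort_trace` with costs.
#' @param ... Unused.
#' @return A ggplot object: per-cycle survival and cumulative expected cost
#'   by category.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  years <- seq_len(object$horizon_cycles) * CYCLE_YEARS
  df <- tibble::tibble(year = years, value = object$survival,
                       series = "survival", panel = "Survival")
  if (!is.null(object$costs)) {
    cum <- object$costs |>
      dplyr::mutate(year = years) |>
      tidyr::pivot_longer(dplyr::all_of(COST_CATEGORIES), names_to = "series",
                          values_to = "cost") |>
      dplyr::group_by(.data$series) |>
      dplyr::mutate(value = cumsum(.data$cost), panel = "Cumulative cost (GBP)") |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("year", "value", "series", "panel")))
    df <- dplyr::bind_rows(df, cum)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Years", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Discount a per-cycle cost stream
#'
#' Present value at an annual rate, with mid-cycle timing by default
#' (cash flows at (k - 0.5) cycles, the health-economics convention) or
#' end-of-cycle timing.
#'
#' @param costs Numeric vector of per-cycle costs (GBP), cycle 1 first.
#' @param annual_rate Annual discount rate (e.g. 0.035).
#' @param timing `"mid"` or `"end"`.
#' @return The discounted sum (GBP).
#' @export
#' @examples
#' discount_stream(rep(100, 20), 0.035)
discount_stream <- function(costs, annual_rate, timing = c("mid", "end")) {
  timing <- match.arg(timing)
  if (!is.numeric(annual_rate) || length(annual_rate) != 1 || is.na(annual_rate) ||
      annual_rate < 0) {
    abort("`annual_rate` must be a nonnegative number",
          class = "scadcost_argument_error")
  }
  if (!length(costs)) return(0)
  delta <- if (timing == "mid") 0.5 else 0
  t_years <- (seq_along(costs) - delta) * CYCLE_YEARS
  sum(costs * (1 + annual_rate)^(-t_years))
}

#' Project 5-year and lifetime costs for a profile
#'
#' Combines the transition structure and the three-category panel cost
#' parameters via the deterministic cohort trace: 5-year cells sum cycles
#' 1-20, lifetime cells sum to the horizon (with a residual-mass warning if
#' survival at the horizon exceeds 1e-4), each reported undiscounted and
#' discounted.
#'
#' @param params A `transition_params` (or coercible).
#' @param cost_params Named list (`total`, `cvd`, `chd`) of
#'   [panel_cost_params()] or [fit_panel()] results.
#' @param profile Named covariate values.
#' @param horizon_cycles Projection horizon (cycles, at least 20; default
#'   400, about 98.6 years).
#' @param rate Annual discount rate.
#' @param timing Discount timing, `"mid"` (default) or `"end"`.
#' @return An object of class `cost_projection`: `five_year` and `lifetime`
#'   tibbles (category, undiscounted, discounted), `life_expectancy`
#'   (years), `five_year_risk`, `survival`, `cost_streams`, and the
#'   conventions used.
#' @export
project <- function(params, cost_params, profile, horizon_cycles = 400,
                    rate = 0.035, timing = c("mid", "end")) {
  timing <- match.arg(timing)
  if (horizon_cycles < 20) {
    abort("`horizon_cycles` must be at least 20 for a 5-year summary",
          class = "scadcost_argument_error")
  }
  cost_params <- resolve_cost_params(cost_params)
  trace <- run_trace(params, profile, horizon_cycles, cost_params)
  residual <- trace$survival[horizon_cycles]
  if (residual > 1e-4) {
    warn(sprintf("survival at horizon is %.2e (> 1e-4); lifetime totals are truncated",
                 residual))
  }
  cell <- function(cycles_idx) {
    purrr::map_dfr(COST_CATEGORIES, function(cat) {
      stream <- trace$costs[[cat]][cycles_idx]
      tibble::tibble(
        category = cat,
        undiscounted = sum(stream),
        discounted = discount_stream(stream, rate, timing)
      )
    })
  }
  structure(
    list(
      five_year = cell(1:20),
      lifetime = cell(seq_len(horizon_cycles)),
      life_expectancy = sum(trace$survival) * CYCLE_YEARS,
      five_year_risk = five_year_risk(params, profile),
      survival = trace$survival,
      cost_streams = trace$costs,
      rate = rate, timing = timing, horizon_cycles = horizon_cycles,
      residual_survival = residual,
      profile = profile
    ),
    class = "cost_projection"
  )
}

#' @export
print.cost_projection <- function(x, ...) {
  cat(sprintf(
    "<cost_projection: LE %.2f years, 5-year CVD risk %.1f%%, horizon %d cycles>\n",
    x$life_expectancy, 100 * x$five_year_risk, x$horizon_cycles))
  cat("  five-year (GBP):\n"); print(x$five_year)
  cat("  lifetime (GBP):\n"); print(x$lifetime)
  invisible(x)
}

#' @rdname project
#' @param x A `cost_projection`.
#' @param ... Unused.
#' @method tidy cost_projection
#' @export
tidy.cost_projection <- function(x, ...) {
  dplyr::bind_rows(
    x$five_year |> dplyr::mutate(horizon = "five_year", .before = 1),
    x$lifetime |> dplyr::mutate(horizon = "lifetime", .before = 1)
  ) |>
    tidyr::pivot_longer(c("undiscounted", "discounted"),
                        names_to = "discounting", values_to = "cost")
}

#' @rdname project
#' @method glance cost_projection
#' @export
glance.cost_projection <- function(x, ...) {
  tibble::tibble(
    life_expectancy = x$life_expectancy,
    five_year_risk = x$five_year_risk,
    horizon_cycles = x$horizon_cycles,
    rate = x$rate,
    timing = x$timing,
    residual_survival = x$residual_survival
  )
}

#' Microsimulation oracle for the cohort trace
#'
#' Samples `n` individual trajectories from the same one-cycle transition
#' probabilities and mean cost structure as [run_trace()]/[project()] and
#' returns Monte Carlo estimates with standard errors, plus the sampled
#' state-occupancy fractions for occupancy-level comparison against the
#' deterministic trace.
#'
#' @inheritParams project
#' @param n Number of simulated individuals (at least 1000).
#' @param seed Integer seed; deterministic given the seed.
#' @return An object of class `microsim_projection` with `five_year` and
#'   `lifetime` tibbles (mean and standard error per category and
#'   discounting), `life_expectancy` and `five_year_risk` (each with
#'   standard errors), and `occupancy` (cycles x states fraction matrix).
#' @export
microsimulate <- function(params, cost_params, profile, n = 10000, seed = 1L,
                          horizon_cycles = 400, rate = 0.035,
                          timing = c("mid", "end")) {
  timing <- match.arg(timing)
  if (n < 1000) {
    abort("`n` must be at least 1000 for a usable oracle",
          class = "scadcost_argument_error")
  }
  params <- as_transition_params(params)
  cost_params <- resolve_cost_params(cost_params)
  states <- scad_states()
  S <- length(states)
  P <- transition_matrix(params, profile)
  cumP <- t(apply(P, 1, cumsum))
  death_idx <- match(DEATH_EVENTS, states)
  stable_idx <- match("stable", states)
  b1_idx <- match(paste0(NONFATAL_EVENTS, "_b1"), states)

  inc <- lapply(cost_params, state_increments)
  ce <- vapply(cost_params, function(cp) profile_cost_effect(cp, profile), numeric(1))
  di <- lapply(cost_params, function(cp) cp$death_increments)
  delta <- if (timing == "mid") 0.5 else 0

  set.seed(seed)
  state <- rep(stable_idx, n)
  cum_undisc <- matrix(0, n, 3, dimnames = list(NULL, COST_CATEGORIES))
  cum_disc <- cum_undisc
  fy_undisc <- fy_disc <- NULL
  alive_cycles <- numeric(n)
  cvd_event_20 <- logical(n)
  occupancy <- matrix(0, horizon_cycles, S, dimnames = list(NULL, states))

  for (t in seq_len(horizon_cycles)) {
    u <- runif(n)
    prev <- state
    for (s in setdiff(unique(prev), death_idx)) {
      idx <- which(prev == s)
      state[idx] <- findInterval(u[idx], cumP[s, ]) + 1L
    }
    alive_end <- !(state %in% death_idx)
    newly_dead <- !alive_end & !(prev %in% death_idx)
    if (t <= 20) {
      hit <- prev == stable_idx &
        (state %in% b1_idx | state == death_idx[1])
      cvd_event_20 <- cvd_event_20 | hit
    }
    alive_cycles <- alive_cycles + alive_end
    df_t <- (1 + rate)^(-(t - delta) * CYCLE_YEARS)
    for (ci in seq_along(COST_CATEGORIES)) {
      cat <- COST_CATEGORIES[ci]
      cp <- cost_params[[cat]]
      base_t <- cp$baseline + cp$trend * (t - 1) + ce[[ci]]
      contrib <- numeric(n)
      contrib[alive_end] <- base_t + inc[[cat]][state[alive_end]]
      if (any(newly_dead)) {
        dtyp <- states[state[newly_dead]]
        contrib[newly_dead] <- base_t + di[[cat]][dtyp]
      }
      cum_undisc[, ci] <- cum_undisc[, ci] + contrib
      cum_disc[, ci] <- cum_disc[, ci] + contrib * df_t
    }
    occupancy[t, ] <- tabulate(state, S) / n
    if (t == 20) {
      fy_undisc <- cum_undisc
      fy_disc <- cum_disc
    }
  }
  if (is.null(fy_undisc)) { fy_undisc <- cum_undisc; fy_disc <- cum_disc }

  summarize_cells <- function(ud, dc) {
    purrr::map_dfr(seq_along(COST_CATEGORIES), function(ci) {
      tibble::tibble(
        category = COST_CATEGORIES[ci],
        undiscounted = mean(ud[, ci]),
        discounted = mean(dc[, ci]),
        se_undiscounted = sd(ud[, ci]) / sqrt(n),
        se_discounted = sd(dc[, ci]) / sqrt(n)
      )
    })
  }
  life_years <- alive_cycles * CYCLE_YEARS
  structure(
    list(
      five_year = summarize_cells(fy_undisc, fy_disc),
      lifetime = summarize_cells(cum_undisc, cum_disc),
      life_expectancy = mean(life_years),
      life_expectancy_se = sd(life_years) / sqrt(n),
      five_year_risk = mean(cvd_event_20),
      five_year_risk_se = sd(cvd_event_20) / sqrt(n),
      occupancy = occupancy,
      n = n, seed = seed, rate = rate, timing = timing,
      horizon_cycles = horizon_cycles
    ),
    class = "microsim_projection"
  )
}

#' @export
print.microsim_projection <- function(x, ...) {
  cat(sprintf("<microsim_projection: n = %d, LE %.2f years, 5-year risk %.3f>\n",
              x$n, x$life_expectancy, x$five_year_risk))
  cat("  lifetime (GBP):\n"); print(x$lifetime)
  invisible(x)
}
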