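# Six-state (plus tunnel) Markov structure on the 90-day cycle grid:
# Stable -> {AMI, ischaemic stroke, haemorrhagic stroke, CVD death,
# non-CVD death}; after a non-fatal event only the two death transitions
# remain. Tunnel states (band 1-4, then long-run) realize the
# time-since-event cost bands inside the Markov chain.

#' Markov state space
#'
#' One stable state; four one-cycle tunnel states plus a long-run state for
#' each non-fatal event type; two absorbing death states (18 states).
#'
#' @return Character vector of state names.
#' @export
scad_states <- function() {
  c("stable",
    unlist(lapply(NONFATAL_EVENTS, function(ev) {
      c(paste0(ev, "_b", 1:4), paste0(ev, "_long"))
    })),
    DEATH_EVENTS)
}

#' Transition hazard parameters
#'
#' Container for cause-specific per-cycle hazards: a log baseline rate and
#' proportional log-hazard ratios per covariate for each of the five first
#' events (from the stable state) and the two death transitions from each
#' post-event phase.
#'
#' @param first_event Named list over `ami`, `ischaemic_stroke`,
#'   `haemorrhagic_stroke`, `cvd_death`, `noncvd_death`; each element
#'   `list(log_base, loghr)`.
#' @param post_event Named list over the three non-fatal event types, each
#'   with `cvd_death` and `noncvd_death` elements of the same shape.
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(first_event, post_event) {
  hp <- list(first_event = first_event, post_event = post_event)
  validate_hazard_params(hp)
  structure(hp, class = "transition_params")
}

#' Coerce hazard parameters to `transition_params`
#'
#' @param x A `transition_params` or a raw list with `first_event` and
#'   `post_event` elements (for example `sim_config()$hazard_params`).
#' @return A `transition_params` object.
#' @export
as_transition_params <- function(x) {
  if (inherits(x, "transition_params")) return(x)
  transition_params(x$first_event, x$post_event)
}

# Hazards for one profile: list(first = named numeric(5),
# post = list(ev -> named numeric(2))).
profile_hazards <- function(params, profile) {
  design <- tibble::as_tibble(as.list(unlist(profile)))
  first <- hazard_matrix(params$first_event[FIRST_EVENTS], design)[1, ]
  post <- lapply(NONFATAL_EVENTS, function(ev) {
    hazard_matrix(params$post_event[[ev]][DEATH_EVENTS], design)[1, ]
  })
  names(post) <- NONFATAL_EVENTS
  list(first = first, post = post)
}

# Competing-risk split of one cycle: cause-specific probabilities
# p_c = h_c/H * (1 - exp(-H)) and the stay probability exp(-H).
competing_split <- function(h) {
  H <- sum(h)
  if (H <= 0) return(list(p = h * 0, stay = 1))
  list(p = h / H * (1 - exp(-H)), stay = exp(-H))
}

#' One-cycle transition probabilities
#'
#' Builds the transition probability row for one state (or the full matrix
#' when `state` is `NULL`) for a covariate profile. Covariates are
#' time-invariant, so the matrix does not depend on the cycle; the `cycle`
#' argument is kept for interface stability. Rows are nonnegative and sum
#' to one; death rows are unit mass on themselves.
#'
#' @param params A `transition_params` (or coercible via
#'   [as_transition_params()]).
#' @param profile Named covariate values covering every log-hazard-ratio
#'   name in `params`.
#' @param state A state name from [scad_states()], or `NULL` for the full
#'   matrix.
#' @param cycle Cycle index (unused under time-invariant covariates).
#' @return A named probability vector over successor states, or the full
#'   matrix with states as row and column names.
#' @export
transition_matrix <- function(params, profile, state = NULL, cycle = 1) {
  params <- as_transition_params(params)
  states <- scad_states()
  hz <- profile_hazards(params, profile)
  P <- matrix(0, length(states), length(states), dimnames = list(states, states))

  sp <- competing_split(hz$first)
  P["stable", "stable"] <- sp$stay
  P["stable", "cvd_death"] <- sp$p[["cvd_death"]]
  P["stable", "noncvd_death"] <- sp$p[["noncvd_death"]]
  for (ev in NONFATAL_EVENTS) {
    P["stable", paste0(ev, "_b1")] <- sp$p[[ev]]
    pp <- competing_split(hz$post[[ev]])
    for (b in 1:4) {
      from <- paste0(ev, "_b", b)
      to <- if (b < 4) paste0(ev, "_b", b + 1) else paste0(ev, "_long")
      P[from, to] <- pp$stay
      P[from, "cvd_death"] <- pp$p[["cvd_death"]]
      P[from, "noncvd_death"] <- pp$p[["noncvd_death"]]
    }
    lr <- paste0(ev, "_long")
    P[lr, lr] <- pp$stay
    P[lr, "cvd_death"] <- pp$p[["cvd_death"]]
    P[lr, "noncvd_death"] <- pp$p[["noncvd_death"]]
  }
  P["cvd_death", "cvd_death"] <- 1
  P["noncvd_death", "noncvd_death"] <- 1

  if (is.null(state)) return(P)
  if (!state %in% states) stop_data(paste0("unknown state: ", state))
  P[state, ]
}

# --- maximum likelihood for discrete-cycle competing risks ----------------

# Per-cycle competing exponential rates: a subject contributes exp(-H) per
# event-free cycle and (h_c/H)(1-exp(-H)) in the cycle of event c.
# `n0` = event-free cycles at risk, `outcome` = 0 (none) or cause index,
# X = design with leading intercept column.
fit_competing <- function(n0, outcome, X, cause_names, rate_floor = 1e-8,
                          label = "") {
  C <- length(cause_names)
  p <- ncol(X)
  counts <- tabulate(outcome, nbins = C)
  free_beta <- counts > 0
  if (p > 1) {
    for (ci in which(!free_beta)) {
      warn(sprintf(
        "no observed %s transitions%s; covariate effects dropped to baseline-only",
        cause_names[ci], if (nzchar(label)) paste0(" (", label, ")") else ""))
    }
  }
  # parameter layout: for each cause, intercept then (if free) betas
  par_index <- list(); theta0 <- numeric(0)
  for (ci in seq_len(C)) {
    rate0 <- max(counts[ci] / max(sum(n0) + sum(outcome > 0), 1), rate_floor)
    idx <- length(theta0) + 1L
    if (free_beta[ci] && p > 1) {
      par_index[[ci]] <- idx:(idx + p - 1L)
      theta0 <- c(theta0, log(rate0), rep(0, p - 1))
    } else {
      par_index[[ci]] <- idx
      theta0 <- c(theta0, log(rate0))
    }
  }
  ev <- outcome > 0

  unpack <- function(theta) {
    Theta <- matrix(0, p, C)
    for (ci in seq_len(C)) {
      th <- theta[par_index[[ci]]]
      Theta[seq_along(th), ci] <- th
    }
    Theta
  }
  negll <- function(theta) {
    LP <- X %*% unpack(theta)
    h <- exp(LP)
    H <- rowSums(h)
    ll <- -sum(H * n0)
    if (any(ev)) {
      He <- H[ev]
      ll <- ll + sum(LP[cbind(which(ev), outcome[ev])]) -
        sum(log(He)) + sum(log1p(-exp(-He)))
    }
    -ll
  }
  neggr <- function(theta) {
    LP <- X %*% unpack(theta)
    h <- exp(LP)
    H <- rowSums(h)
    # d loglik / d lp_ic
    D <- -h * n0
    if (any(ev)) {
      He <- H[ev]
      adj <- -h[ev, , drop = FALSE] / He +
        h[ev, , drop = FALSE] * exp(-He) / (1 - exp(-He))
      D[ev, ] <- D[ev, ] + adj
      D[cbind(which(ev), outcome[ev])] <- D[cbind(which(ev), outcome[ev])] + 1
    }
    g <- numeric(length(theta))
    for (ci in seq_len(C)) {
      gi <- drop(crossprod(X, D[, ci]))
      g[par_index[[ci]]] <- gi[seq_along(par_index[[ci]])]
    }
    -g
  }
  lower <- rep(-Inf, length(theta0))
  for (ci in seq_len(C)) lower[par_index[[ci]][1]] <- log(rate_floor)
  opt <- optim(theta0, negll, neggr, method = "L-BFGS-B", lower = lower,
               control = list(maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 52) {
    abort(sprintf("competing-risk fit did not converge (code %d: %s)",
                  opt$convergence, opt$message %||% ""),
          class = "scadcost_convergence_error")
  }
  hess <- tryCatch(stats::optimHess(opt$par, negll, neggr),
                   error = function(e) NULL)
  se <- rep(NA_real_, length(opt$par))
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }
  covar_names <- colnames(X)[-1]
  out <- list()
  for (ci in seq_len(C)) {
    idx <- par_index[[ci]]
    th <- opt$par[idx]; s <- se[idx]
    loghr <- if (length(idx) > 1) setNames(th[-1], covar_names) else
      setNames(numeric(0), character(0))
    loghr_se <- if (length(idx) > 1) setNames(s[-1], covar_names) else
      setNames(numeric(0), character(0))
    out[[cause_names[ci]]] <- list(
      log_base = th[1], loghr = loghr,
      se = list(log_base = s[1], loghr = loghr_se),
      n_events = counts[ci]
    )
  }
  attr(out, "loglik") <- -opt$value
  out
}

#' Fit transition hazards from a cohort
#'
#' Maximum-likelihood estimation of the discrete-cycle cause-specific
#' hazards: first events compete from the stable state over each patient's
#' stable cycles; the two death transitions compete over the post-event
#' cycles of patients whose first event was non-fatal. Covariate effects
#' are proportional on the cause-specific hazards and time-invariant.
#' Transitions with no observed events keep a baseline-only hazard capped
#' at `rate_floor` (with a warning for dropped covariate effects).
#'
#' @param baseline Baseline tibble.
#' @param events Event tibble.
#' @param horizon_cycles Administrative horizon used to close exposure for
#'   event-free patients.
#' @param covariates Design-covariate columns entering every transition.
#' @param rate_floor Lower bound on each baseline rate (events/cycle).
#' @return A `transition_params` object; each transition also carries `se`
#'   (standard errors) and `n_events`.
#' @export
fit_transitions <- function(baseline, events, horizon_cycles,
                            covariates = c("age10c", "sex_female"),
                            rate_floor = 1e-8) {
  if (!nrow(events) || !any(events$event %in% FIRST_EVENTS)) {
    stop_data("no events observed; simulate or supply a larger cohort")
  }
  exits <- patient_exits(baseline, events, horizon_cycles)
  design <- design_covariates(baseline)
  miss <- setdiff(covariates, names(design))
  if (length(miss)) {
    stop_data(paste0("unknown covariate column(s): ", paste(miss, collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1, as.matrix(design[covariates]))

  first <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$cycle, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  idx <- match(first$patient_id, baseline$patient_id)
  outcome1 <- integer(nrow(baseline))
  cyc1 <- exits$exit_cycle   # event-free stable cycles for non-event patients
  is_first_event <- first$event %in% FIRST_EVENTS
  outcome1[idx[is_first_event]] <- match(first$event[is_first_event], FIRST_EVENTS)
  cyc1[idx] <- first$cycle
  n0 <- ifelse(outcome1 > 0, cyc1 - 1L, cyc1)

  fe_fit <- fit_competing(n0, outcome1, X, FIRST_EVENTS, rate_floor,
                          label = "first event")

  pe_fit <- list()
  fnf <- first_nonfatal(events)
  death_after <- events |>
    dplyr::filter(.data$event %in% DEATH_EVENTS) |>
    dplyr::transmute(patient_id = .data$patient_id, death_event = .data$event,
                     death_cycle = .data$cycle)
  for (evt in NONFATAL_EVENTS) {
    sub <- fnf |>
      dplyr::filter(.data$event_type == evt) |>
      dplyr::left_join(death_after, by = "patient_id") |>
      dplyr::left_join(exits, by = "patient_id")
    if (nrow(sub) == 0) {
      # no such events observed: floor both death rates
      pe_fit[[evt]] <- setNames(lapply(DEATH_EVENTS, function(d) {
        list(log_base = log(rate_floor), loghr = setNames(numeric(0), character(0)),
             se = list(log_base = NA_real_, loghr = numeric(0)), n_events = 0L)
      }), DEATH_EVENTS)
      next
    }
    died <- !is.na(sub$death_cycle)
    outcome2 <- ifelse(died, match(sub$death_event, DEATH_EVENTS), 0L)
    outcome2[is.na(outcome2)] <- 0L
    end_cycle <- ifelse(died, sub$death_cycle, sub$exit_cycle)
    n0p <- end_cycle - sub$event_cycle - ifelse(outcome2 > 0, 1L, 0L)
    Xp <- X[match(sub$patient_id, baseline$patient_id), , drop = FALSE]
    pe_fit[[evt]] <- fit_competing(n0p, outcome2, Xp, DEATH_EVENTS, rate_floor,
                                   label = paste("after", evt))
  }
  out <- transition_params(fe_fit, pe_fit)
  attr(out, "covariates") <- covariates
  attr(out, "n") <- nrow(baseline)
  out
}

#' @export
print.transition_params <- function(x, ...) {
  cat("<transition_params>\n  first events (rate/cycle at reference):\n")
  for (ev in FIRST_EVENTS) {
    cat(sprintf("    %-20s %.5f\n", ev, exp(x$first_event[[ev]]$log_base)))
  }
  cat("  post-event death rates (CVD / non-CVD):\n")
  for (ev in NONFATAL_EVENTS) {
    cat(sprintf("    %-20s %.4f / %.4f\n", ev,
                exp(x$post_event[[ev]]$cvd_death$log_base),
                exp(x$post_event[[ev]]$noncvd_death$log_base)))
  }
  invisible(x)
}

#' @rdname fit_transitions
#' @param x A `transition_params`.
#' @param ... Unused.
#' @method tidy transition_params
#' @export
tidy.transition_params <- function(x, ...) {
  rows <- list()
  grab <- function(tr, transition) {
    r <- tibble::tibble(
      transition = transition, term = "log_base",
      estimate = tr$log_base,
      std.error = if (!is.null(tr$se)) tr$se$log_base else NA_real_
    )
    if (length(tr$loghr)) {
      r <- dplyr::bind_rows(r, tibble::tibble(
        transition = transition, term = names(tr$loghr),
        estimate = unname(tr$loghr),
        std.error = if (!is.null(tr$se)) unname(tr$se$loghr) else NA_real_
      ))
    }
    r
  }
  for (ev in FIRST_EVENTS) {
    rows[[length(rows) + 1L]] <- grab(x$first_event[[ev]], paste0("stable->", ev))
  }
  for (ev in NONFATAL_EVENTS) {
    for (d in DEATH_EVENTS) {
      rows[[length(rows) + 1L]] <- grab(x$post_event[[ev]][[d]],
                                        paste0(ev, "->", d))
    }
  }
  dplyr::bind_rows(rows)
}

#' Five-year risk of a first cardiovascular event
#'
#' Probability that the first of AMI, ischaemic or haemorrhagic stroke, or
#' CVD death occurs within 20 cycles (five model years), by cohort-trace
#' absorption accounting with non-CVD death as a competing risk.
#'
#' @param params A `transition_params` (or coercible).
#' @param profile Named covariate values.
#' @param cycles Horizon in cycles (default 20 = five years).
#' @return A probability.
#' @export
five_year_risk <- function(params, profile, cycles = 20) {
  params <- as_transition_params(params)
  hz <- profile_hazards(params, profile)
  sp <- competing_split(hz$first)
  p_sel <- sum(sp$p[c(NONFATAL_EVENTS, "cvd_death")])
  occ <- 1; risk <- 0
  for (k in seq_len(cycles)) {
    risk <- risk + occ * p_sel
    occ <- occ * sp$stay
  }
  risk
}

# Vectorized five-year risk over a cohort (time-invariant hazards admit
# the geometric closed form).
five_year_risk_cohort <- function(params, baseline, cycles = 20) {
  params <- as_transition_params(params)
  design <- design_covariates(baseline)
  h <- hazard_matrix(params$first_event[FIRST_EVENTS], design)
  H <- rowSums(h)
  sel <- rowSums(h[, c(NONFATAL_EVENTS, "cvd_death"), drop = FALSE])
  risk <- ifelse(H > 0, sel / H * (1 - exp(-cycles * H)), 0)
  as.numeric(risk)
}

#' Model life expectancy
#'
#' Sum of per-cycle survival probabilities from the cohort trace times the
#' cycle length in years (end-of-cycle convention: death in cycle 1 yields
#' zero life expectancy).
#'
#' @param params A `transition_params` (or coercible).
#' @param profile Named covariate values.
#' @param horizon_cycles Truncation horizon; a warning reports the residual
#'   survival mass if more than 1e-4 remains.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(params, profile, horizon_cycles = 400) {
  trace <- run_trace(params, profile, horizon_cycles)
  sum(trace$survival) * CYCLE_YEARS
}
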