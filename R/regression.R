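# First-year cost regression: gamma GLM with log link fitted on multiply
# imputed data sets, pooled by Rubin's rules, with covariate effects
# reported as natural-scale (GBP) increments via recycled predictions.

#' Multiple imputation by chained equations
#'
#' Fills missing values in the numeric columns of `data` by chained
#' equations: predictive mean matching (type-1 matching, 5 donors) for
#' continuous variables and Bayesian logistic draws for binary (0/1)
#' variables. Parameters are drawn from their approximate posterior at each
#' step, so imputed values differ across the `m` completed data sets while
#' observed entries are identical in all of them.
#'
#' @param data A tibble; all columns except `id_cols` must be numeric.
#'   Include the analysis outcome so the imputation model is congenial
#'   with the analysis model.
#' @param m Number of imputations (at least 2).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_iter Chained-equation sweeps per imputation.
#' @param pmm_k Donor pool size for predictive mean matching.
#' @param id_cols Columns excluded from the imputation model and passed
#'   through unchanged.
#' @return A list of `m` completed tibbles with attribute `"seed"`.
#' @export
impute_cohort <- function(data, m = 5, seed = 1L, n_iter = 5, pmm_k = 5,
                          id_cols = "patient_id") {
  if (m < 2) stop_config("`m` must be at least 2", field = "m")
  id_cols <- intersect(id_cols, names(data))
  work <- data[setdiff(names(data), id_cols)]
  if (!all(vapply(work, is.numeric, logical(1)))) {
    stop_data("all imputation-model columns must be numeric")
  }
  all_missing <- names(work)[vapply(work, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop_data(paste0("column(s) entirely missing, cannot impute: ",
                     paste(all_missing, collapse = ", ")))
  }
  mis_cols <- names(work)[vapply(work, anyNA, logical(1))]
  if (!length(mis_cols)) {
    out <- replicate(m, data, simplify = FALSE)
    attr(out, "seed") <- seed
    return(out)
  }
  if (length(mis_cols) == ncol(work)) {
    stop_data("at least one fully observed covariate is required")
  }
  is_binary <- vapply(work, function(x) {
    all(na.omit(x) %in% c(0, 1))
  }, logical(1))

  set.seed(seed)
  mat0 <- as.matrix(work)
  obs_idx <- lapply(mis_cols, function(j) which(!is.na(mat0[, j])))
  names(obs_idx) <- mis_cols

  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    mat <- mat0
    for (j in mis_cols) {  # initialize from observed marginals
      nas <- is.na(mat[, j])
      mat[nas, j] <- sample(mat[obs_idx[[j]], j], sum(nas), replace = TRUE)
    }
    for (iter in seq_len(n_iter)) {
      for (j in mis_cols) {
        oi <- obs_idx[[j]]
        mi <- setdiff(seq_len(nrow(mat)), oi)
        X <- cbind(1, mat[, setdiff(colnames(mat), j), drop = FALSE])
        y <- mat[oi, j]
        if (is_binary[[j]]) {
          fit <- suppressWarnings(glm.fit(X[oi, , drop = FALSE], y,
                                          family = binomial()))
          bh <- fit$coefficients
          bh[is.na(bh)] <- 0
          beta <- draw_coef(bh, glm_fit_vcov(fit, X[oi, , drop = FALSE]))
          p <- 1 / (1 + exp(-drop(X[mi, , drop = FALSE] %*% beta)))
          mat[mi, j] <- as.numeric(runif(length(mi)) < p)
        } else {
          Xo <- X[oi, , drop = FALSE]
          qrX <- qr(Xo)
          beta_hat <- qr.coef(qrX, y)
          beta_hat[is.na(beta_hat)] <- 0
          res <- y - drop(Xo %*% beta_hat)
          df <- max(length(oi) - qrX$rank, 1)
          sigma2 <- sum(res^2) / rchisq(1, df)
          XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
          beta <- draw_coef(beta_hat, sigma2 * XtXinv)
          pred_obs <- drop(Xo %*% beta_hat)
          pred_mis <- drop(X[mi, , drop = FALSE] %*% beta)
          mat[mi, j] <- pmm_match(pred_obs, y, pred_mis, pmm_k)
        }
      }
    }
    comp <- data
    for (j in mis_cols) comp[[j]] <- mat[, j]
    completed[[imp]] <- comp
  }
  attr(completed, "seed") <- seed
  completed
}

# Type-1 predictive mean matching: for each missing prediction, find its k
# nearest observed predictions (a contiguous window in sorted order, found
# by a vectorized two-pointer sweep) and sample one donor's observed value.
pmm_match <- function(pred_obs, y_obs, pred_mis, k = 5) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo <- y_obs[ord]
  nm <- length(pred_mis); no <- length(po)
  k <- min(k, no)
  pos <- findInterval(pred_mis, po)
  L <- pos; R <- pos + 1L
  sel <- matrix(1L, nm, k)
  for (step in seq_len(k)) {
    dl <- ifelse(L >= 1L, pred_mis - po[pmax(L, 1L)], Inf)
    dr <- ifelse(R <= no, po[pmin(R, no)] - pred_mis, Inf)
    take_left <- dl <= dr
    sel[, step] <- ifelse(take_left, L, R)
    L <- L - as.integer(take_left)
    R <- R + as.integer(!take_left)
  }
  pick <- sel[cbind(seq_len(nm), sample.int(k, nm, replace = TRUE))]
  yo[pick]
}

draw_coef <- function(beta_hat, vc) {
  vc <- (vc + t(vc)) / 2
  ch <- tryCatch(chol(vc), error = function(e) {
    chol(vc + diag(1e-10, nrow(vc)))
  })
  drop(beta_hat + t(ch) %*% rnorm(length(beta_hat)))
}

glm_fit_vcov <- function(fit, X) {
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  chol2inv(chol(XtWX + diag(1e-8, ncol(X))))
}

#' Fit a gamma GLM with log link
#'
#' Estimates the impact of baseline covariates on positive, right-skewed
#' annual costs: the log of the mean cost is linear in the covariates and
#' the response is gamma distributed. Zero costs, which lie outside the
#' gamma support, are floored at a configurable small positive value
#' (default GBP 0.01).
#'
#' @param data A completed (no missing values) tibble containing the
#'   response and covariates.
#' @param formula Model formula, response on the GBP scale.
#' @param zero_floor Replacement for non-positive responses.
#' @return An object of class `gamma_fit`: coefficients, covariance,
#'   dispersion, `n`, and the formula.
#' @export
#' @examples
#' d <- tibble::tibble(cost = c(100, 200, 300))
#' fit_gamma_log(d, cost ~ 1)$coefficients  # log(200)
fit_gamma_log <- function(data, formula, zero_floor = 0.01) {
  vars <- all.vars(formula)
  resp <- vars[1]
  if (anyNA(data[intersect(vars, names(data))])) {
    stop_data("`data` must be complete; impute first")
  }
  d <- data
  if (any(d[[resp]] <= 0)) d[[resp]] <- pmax(d[[resp]], zero_floor)
  fit <- glm(formula = formula, data = d, family = Gamma(link = "log"))
  if (!fit$converged) {
    abort(sprintf("gamma GLM did not converge after %d iterations", fit$iter),
          class = "scadcost_convergence_error")
  }
  if (any(is.na(coef(fit)))) {
    abort(paste0("design is singular; aliased terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "scadcost_singular_error")
  }
  structure(
    list(
      coefficients = coef(fit),
      vcov = vcov(fit),
      dispersion = summary(fit)$dispersion,
      n = nrow(data),
      formula = formula
    ),
    class = "gamma_fit"
  )
}

#' Pool fits across imputations with Rubin's rules
#'
#' Combines M point estimates and covariance matrices: the pooled estimate
#' is the mean of the estimates, the within-imputation variance W is the
#' mean of the variances, the between-imputation variance B is the sample
#' variance of the estimates, and the total variance is
#' T = W + (1 + 1/M) B. Confidence intervals use a normal approximation on
#' the log (link) scale.
#'
#' @param fits A list of at least two `gamma_fit` objects (or any objects
#'   with `coefficients` and `vcov`) with identical coefficient names.
#' @param conf_level Confidence level for the pooled intervals.
#' @return An object of class `pooled_fit`.
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  if (length(fits) < 2) stop_config("need at least 2 fits to pool", field = "fits")
  terms <- names(fits[[1]]$coefficients)
  for (f in fits) {
    if (!identical(names(f$coefficients), terms)) {
      stop_data("fits have non-conformable coefficient vectors")
    }
  }
  M <- length(fits)
  est <- vapply(fits, function(f) f$coefficients, numeric(length(terms)))
  est <- matrix(est, nrow = length(terms))
  qbar <- rowMeans(est)
  W <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / M
  centered <- est - qbar
  B <- tcrossprod(centered) / (M - 1)
  Tmat <- W + (1 + 1 / M) * B
  se <- sqrt(diag(Tmat))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      coefficients = setNames(qbar, terms),
      within = W, between = B, total = Tmat,
      se = setNames(se, terms),
      ci_lower = setNames(qbar - z * se, terms),
      ci_upper = setNames(qbar + z * se, terms),
      m = M, conf_level = conf_level,
      formula = fits[[1]]$formula,
      n = fits[[1]]$n
    ),
    class = "pooled_fit"
  )
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled_fit: %d imputations, %d terms, n = %s>\n",
              x$m, length(x$coefficients), x$n %||% "?"))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname pool_rubin
#' @param x A `pooled_fit`.
#' @param ... Unused.
#' @method tidy pooled_fit
#' @export
tidy.pooled_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper)
  )
}

#' @rdname pool_rubin
#' @method glance pooled_fit
#' @export
glance.pooled_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    nterms = length(x$coefficients),
    n = x$n %||% NA_integer_,
    conf.level = x$conf_level
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural-scale (GBP) covariate increments
#'
#' Transforms pooled log-scale coefficients into average GBP increments by
#' recycled predictions: for a binary covariate, the increment is the mean
#' over the cohort of the predicted cost with the covariate set to 1 minus
#' the prediction with it set to 0; for a continuous covariate the shift is
#' one reporting unit (configurable via `units`). Interval bounds apply the
#' same transform at the coefficient's confidence limits (endpoint
#' transformation), which respects the positivity of predicted costs.
#'
#' @param pooled A [pool_rubin()] result.
#' @param baseline_table A completed covariate table to recycle predictions
#'   over (for example one imputed data set).
#' @param units Named numeric vector of reporting units for continuous
#'   covariates (default 1 unit).
#' @return A tibble: `term`, `increment` (GBP), `conf.low`, `conf.high`,
#'   `reference`.
#' @export
to_natural_scale <- function(pooled, baseline_table, units = NULL) {
  rhs <- stats::delete.response(stats::terms(pooled$formula))
  X <- model.matrix(rhs, data = baseline_table)
  miss <- setdiff(colnames(X), names(pooled$coefficients))
  if (length(miss)) {
    stop_data(paste0("covariate absent from pooled fit: ", paste(miss, collapse = ", ")))
  }
  beta <- pooled$coefficients[colnames(X)]
  terms_out <- setdiff(colnames(X), "(Intercept)")
  inc_for <- function(term, beta_term) {
    b <- beta
    b[term] <- beta_term
    x <- X
    is_bin <- all(X[, term] %in% c(0, 1))
    if (is_bin) {
      x1 <- x; x1[, term] <- 1
      x0 <- x; x0[, term] <- 0
      mean(exp(drop(x1 %*% b))) - mean(exp(drop(x0 %*% b)))
    } else {
      unit <- if (!is.null(units) && term %in% names(units)) units[[term]] else 1
      x1 <- x; x1[, term] <- x1[, term] + unit
      mean(exp(drop(x1 %*% b))) - mean(exp(drop(x %*% b)))
    }
  }
  purrr::map_dfr(terms_out, function(term) {
    is_bin <- all(X[, term] %in% c(0, 1))
    unit <- if (!is.null(units) && term %in% names(units)) units[[term]] else 1
    tibble::tibble(
      term = term,
      increment = inc_for(term, beta[term]),
      conf.low = inc_for(term, pooled$ci_lower[term]),
      conf.high = inc_for(term, pooled$ci_upper[term]),
      reference = if (is_bin) "absent (0)" else sprintf("per %g unit(s)", unit)
    )
  })
}

#' First-year cost regression pipeline
#'
#' End-to-end convenience wrapper: joins per-patient first-year cost totals
#' onto the baseline covariates, multiply imputes missing biomarkers (with
#' log cost as an auxiliary predictor), fits the gamma log-link GLM on each
#' completed data set, pools with Rubin's rules, and transforms the pooled
#' effects to GBP increments.
#'
#' @param baseline Baseline tibble (may contain missing biomarkers).
#' @param totals Tibble with `patient_id` and `total_cost` (first-year GBP).
#' @param formula Model formula; default uses sex, age, diagnosis,
#'   comorbidities and all biomarker columns.
#' @param m Number of imputations.
#' @param seed Integer seed.
#' @param units Reporting units passed to [to_natural_scale()].
#' @return List with `pooled` (class `pooled_fit`), `effects` (natural
#'   scale tibble), and `imputations`.
#' @export
fit_first_year_costs <- function(baseline, totals, formula = NULL, m = 5,
                                 seed = 1L, units = c(age10c = 1)) {
  design <- design_covariates(baseline)
  design$patient_id <- baseline$patient_id
  data <- dplyr::inner_join(design, totals, by = "patient_id")
  if (is.null(formula)) {
    covars <- setdiff(names(design), "patient_id")
    formula <- as.formula(paste("total_cost ~", paste(covars, collapse = " + ")))
  }
  data$log_cost_aux <- log(pmax(data$total_cost, 0.01))
  imp_input <- data[c("patient_id", setdiff(all.vars(formula), "total_cost"),
                      "log_cost_aux")]
  imps <- impute_cohort(imp_input, m = m, seed = seed)
  fits <- lapply(imps, function(d) {
    d$total_cost <- data$total_cost
    fit_gamma_log(d, formula)
  })
  pooled <- pool_rubin(fits)
  effects <- to_natural_scale(pooled, imps[[1]], units = units)
  list(pooled = pooled, effects = effects, imputations = imps)
}

#' Forest plot of natural-scale cost increments
#'
#' @param effects Tibble from [to_natural_scale()].
#' @return A ggplot object.
#' @export
plot_cost_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$increment,
                                        y = stats::reorder(.data$term, .data$increment))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Incremental first-year cost (GBP)", y = NULL) +
    ggplot2::theme_minimal()
}
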