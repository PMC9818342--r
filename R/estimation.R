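#' Fitting specification
#'
#' Declares which parameters of a model are estimated and which are fixed,
#' with optional starting values, per-parameter bounds and residual
#' weighting. Free and fixed names must be disjoint; each fitter checks the
#' union covers its model's parameter set.
#'
#' @param free Character vector of parameter names to estimate.
#' @param fixed Named list of parameters held at fixed values.
#' @param start Named list of starting values for free parameters (optional;
#'   defaults are model-specific, with multi-start for potency parameters).
#' @param lower,upper Named lists of bounds for free parameters (optional).
#' @param weighting `"none"` (ordinary least squares on percent viability)
#'   or `"proportional"` (residuals scaled by the model prediction).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free, fixed = list(), start = list(),
                     lower = list(), upper = list(),
                     weighting = c("none", "proportional")) {
  weighting <- match.arg(weighting)
  if (length(intersect(free, names(fixed))) > 0) {
    stop("free and fixed parameter names must be disjoint: ",
         paste(intersect(free, names(fixed)), collapse = ", "))
  }
  structure(list(free = free, fixed = fixed, start = start,
                 lower = lower, upper = upper, weighting = weighting),
            class = "fit_spec")
}

# Positive parameters are estimated on the log scale; r0 and imax stay on
# the natural scale with box bounds.
.log_scale_params <- c("ic50", "gamma", "kg", "smax", "sc50", "tau", "psi")

.default_bounds <- list(
  r0    = c(1e-6, 1e4),
  imax  = c(1e-6, 1),
  ic50  = c(1e-9, 1e9),
  gamma = c(0.05, 20),
  kg    = c(1e-5, 1),
  smax  = c(1e-6, 10),
  sc50  = c(1e-9, 1e9),
  tau   = c(1e-3, 1e3),
  psi   = c(0.01, 100)
)

.to_internal <- function(theta) {
  phi <- ifelse(names(theta) %in% .log_scale_params, log(theta), theta)
  names(phi) <- names(theta)
  phi
}
.from_internal <- function(phi) {
  th <- ifelse(names(phi) %in% .log_scale_params, exp(phi), phi)
  names(th) <- names(phi)
  th
}

.bounds_for <- function(free, spec) {
  lo <- vapply(free, function(p) {
    if (!is.null(spec$lower[[p]])) spec$lower[[p]] else .default_bounds[[p]][1]
  }, numeric(1))
  hi <- vapply(free, function(p) {
    if (!is.null(spec$upper[[p]])) spec$upper[[p]] else .default_bounds[[p]][2]
  }, numeric(1))
  list(lower = lo, upper = hi)
}

# Multi-start bounded Levenberg-Marquardt over named natural-scale
# parameters. resid_fn receives the full parameter vector (free + fixed) and
# returns residuals; non-finite residuals are penalised so a failed forward
# simulation does not abort the fit.
.ls_fit <- function(resid_fn, start_sets, fixed, lower, upper) {
  free <- names(start_sets[[1]])
  phi_lower <- .to_internal(stats::setNames(lower, free))
  phi_upper <- .to_internal(stats::setNames(upper, free))
  fixed_vec <- unlist(fixed)
  obj <- function(phi) {
    names(phi) <- free
    theta <- c(.from_internal(phi), fixed_vec)
    r <- resid_fn(theta)
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  for (st in start_sets) {
    st <- pmin(pmax(st, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = .to_internal(st), lower = phi_lower, upper = phi_upper,
      fn = obj,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  best$phi_lower <- phi_lower
  best$phi_upper <- phi_upper
  best
}

.make_fit_result <- function(fit, free, fixed, n_obs, model) {
  phi <- stats::setNames(fit$par, free)
  est <- .from_internal(phi)
  n_free <- length(free)
  covariance <- NULL
  if (n_obs > n_free) {
    sigma2 <- fit$deviance / (n_obs - n_free)
    # parameters pinned at a bound have their Jacobian column zeroed by the
    # optimizer (no valid Wald SE); invert J'J over the active subset only
    act <- which(diag(as.matrix(fit$hessian)) > 0)
    if (length(act) > 0) {
      cov_act <- try(sigma2 * chol2inv(chol(fit$hessian[act, act,
                                                        drop = FALSE])),
                     silent = TRUE)
      if (!inherits(cov_act, "try-error") && all(is.finite(cov_act))) {
        cov_phi <- matrix(NA_real_, n_free, n_free)
        cov_phi[act, act] <- cov_act
        d <- ifelse(free %in% .log_scale_params, est, 1)
        covariance <- cov_phi * outer(d, d)  # delta method, elementwise
        dimnames(covariance) <- list(free, free)
      }
    }
  }
  lo <- .from_internal(stats::setNames(fit$phi_lower, free))
  hi <- .from_internal(stats::setNames(fit$phi_upper, free))
  at_bound <- free[est <= lo * (1 + 1e-6) + 1e-12 | est >= hi * (1 - 1e-6)]
  res <- structure(list(
    model = model,
    estimates = est,
    fixed = fixed,
    se = stats::setNames(rep(NA_real_, n_free), free),
    rse_pct = stats::setNames(rep(NA_real_, n_free), free),
    objective = fit$deviance,
    n_obs = n_obs,
    n_free = n_free,
    converged = fit$info %in% 1:4,
    boundary = at_bound,
    covariance = covariance,
    rss_trace = fit$rsstrace,
    message = fit$message
  ), class = "fit_result")
  compute_rse(res)
}

#' Relative standard errors for a fit
#'
#' Populates standard errors and percent relative standard errors
#' (`100 * se / |estimate|`) from the residual-variance-scaled inverse of
#' J'J accumulated during the least-squares fit. With a singular Jacobian
#' the RSEs are reported as `NA` and the fit is still returned.
#'
#' @param result A `fit_result`.
#' @return The `fit_result` with `se` and `rse_pct` filled in.
#' @export
compute_rse <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  if (is.null(result$covariance)) return(result)
  v <- diag(result$covariance)
  v[v < 0] <- NA_real_
  se <- sqrt(v)
  result$se <- stats::setNames(se, names(result$estimates))
  result$rse_pct <- 100 * se / abs(result$estimates)
  result
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result:", x$model, ">\n")
  cat(sprintf("  converged: %s   RSS: %.6g   n = %d\n",
              x$converged, x$objective, x$n_obs))
  tab <- data.frame(estimate = x$estimates, rse_pct = x$rse_pct)
  print(round(tab, 6))
  if (length(x$boundary)) {
    cat("  at boundary:", paste(x$boundary, collapse = ", "), "\n")
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

.weight_resid <- function(obs, pred, weighting) {
  if (weighting == "proportional") (obs - pred) / pmax(pred, 1e-8)
  else obs - pred
}

.merge_start <- function(defaults, spec) {
  for (p in names(spec$start)) defaults[[p]] <- spec$start[[p]]
  defaults
}

# Cross user/default starts with multi-start candidate lists into a list of
# named start vectors.
.start_sets <- function(base, multi) {
  sets <- list(unlist(base))
  for (p in names(multi)) {
    sets <- unlist(lapply(sets, function(s) {
      lapply(multi[[p]], function(v) { s[p] <- v; s })
    }), recursive = FALSE)
  }
  sets
}

#' Fit the inhibitory Hill model to concentration-response data
#'
#' Ordinary (or proportionally weighted) least squares on percent viability
#' at a single time point. IC50 is estimated on the log scale internally and
#' reported on the natural scale; five log-spaced IC50 starting values
#' spanning the tested concentration range guard against local minima.
#' The default specification follows the cisplatin fitting pattern
#' (`r0 = 100` and `gamma = 1` fixed, `imax` and `ic50` free); pass a
#' [fit_spec()] with all four parameters free for cimetidine-style fits.
#'
#' @param data `data.frame` with columns `conc` (uM) and `viability` (%):
#'   see [as_single_agent()] for extracting this from tidy plate records.
#' @param spec A [fit_spec()]; default fits `imax` and `ic50`.
#' @return A `fit_result`.
#' @export
#' @examples
#' truth <- reference_hill("Huh7", "CIS")
#' d <- data.frame(conc = c(0.05, 0.17, 0.6, 2.1, 7.2, 25))
#' d$viability <- hill_response(truth, d$conc)
#' fit_hill(d)
fit_hill <- function(data, spec = fit_spec(free = c("imax", "ic50"),
                                           fixed = list(r0 = 100, gamma = 1))) {
  stopifnot(all(c("conc", "viability") %in% names(data)))
  pars <- c("r0", "imax", "ic50", "gamma")
  .check_spec_complete(spec, pars)
  if (length(unique(data$conc)) < 4) {
    stop("need >= 4 distinct concentrations to fit a Hill curve")
  }
  if (stats::sd(data$viability) == 0 && "r0" %in% spec$free) {
    stop("degenerate data: all responses identical with r0 free")
  }
  conc <- data$conc
  obs <- data$viability
  resid_fn <- function(theta) {
    cg <- conc^theta[["gamma"]]
    pred <- theta[["r0"]] *
      (1 - theta[["imax"]] * cg / (theta[["ic50"]]^theta[["gamma"]] + cg))
    .weight_resid(obs, pred, spec$weighting)
  }
  cpos <- conc[conc > 0]
  base <- .merge_start(list(r0 = max(obs), imax = 0.8,
                            ic50 = exp(mean(log(range(cpos)))), gamma = 1),
                       spec)[spec$free]
  multi <- list()
  if ("ic50" %in% spec$free && is.null(spec$start$ic50)) {
    multi$ic50 <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = 5))
  }
  if ("gamma" %in% spec$free && is.null(spec$start$gamma)) {
    multi$gamma <- c(1, 3)
  }
  b <- .bounds_for(spec$free, spec)
  fit <- .ls_fit(resid_fn, .start_sets(base, multi), spec$fixed,
                 b$lower, b$upper)
  .make_fit_result(fit, spec$free, spec$fixed, nrow(data), "hill")
}

.check_spec_complete <- function(spec, pars) {
  have <- union(spec$free, names(spec$fixed))
  missing <- setdiff(pars, have)
  if (length(missing)) {
    stop("fit_spec must cover parameters: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(have, pars)
  if (length(extra)) {
    stop("unknown parameters in fit_spec: ", paste(extra, collapse = ", "))
  }
}

#' Fit the exponential growth model to control time courses
#'
#' Least-squares estimate of the first-order growth rate constant `kg` from
#' untreated-cell viability, `R(t) = r0 * exp(kg * t)`.
#'
#' @param data `data.frame` with columns `time` (h) and `viability` (%).
#' @param spec A [fit_spec()]; default estimates `kg` with `r0 = 100` fixed.
#' @return A `fit_result`.
#' @export
fit_growth <- function(data, spec = fit_spec(free = "kg",
                                             fixed = list(r0 = 100))) {
  stopifnot(all(c("time", "viability") %in% names(data)))
  .check_spec_complete(spec, c("kg", "r0"))
  tt <- data$time
  obs <- data$viability
  resid_fn <- function(theta) {
    .weight_resid(obs, theta[["r0"]] * exp(theta[["kg"]] * tt),
                  spec$weighting)
  }
  kg0 <- if (!is.null(spec$start$kg)) spec$start$kg else {
    ok <- obs > 0 & tt > 0
    if (sum(ok) >= 2) {
      max(1e-4, stats::coef(stats::lm(log(obs[ok]) ~ tt[ok]))[2])
    } else 0.01
  }
  base <- .merge_start(list(kg = kg0, r0 = max(obs[tt == min(tt)])),
                       spec)[spec$free]
  b <- .bounds_for(spec$free, spec)
  fit <- .ls_fit(resid_fn, list(unlist(base)), spec$fixed, b$lower, b$upper)
  .make_fit_result(fit, spec$free, spec$fixed, nrow(data), "growth")
}

#' Estimate the static interaction parameter psi
#'
#' Fits the competitive interaction model to combination viability data with
#' both drugs' Hill parameters fixed (taken from the single-agent fits, as
#' in the sequential workflow) and psi as the sole free parameter.
#'
#' @param data `data.frame` with columns `conc_a`, `conc_b` (uM) and
#'   `viability` (%); only rows with both concentrations > 0 are used and at
#'   least one such row is required. See [as_combination()].
#' @param drug_a,drug_b Fixed [hill_params()] for the two agents.
#' @param r0 Baseline viability for combinations (default 100%).
#' @param psi_on Which IC50(s) psi scales; see [interaction_params()].
#' @param weighting Residual weighting, as in [fit_spec()].
#' @return A `fit_result` with the psi estimate.
#' @export
fit_interaction_static <- function(data, drug_a, drug_b, r0 = 100,
                                   psi_on = c("both", "a"),
                                   weighting = c("none", "proportional")) {
  stopifnot(all(c("conc_a", "conc_b", "viability") %in% names(data)))
  psi_on <- match.arg(psi_on)
  weighting <- match.arg(weighting)
  combo <- data[data$conc_a > 0 & data$conc_b > 0, , drop = FALSE]
  if (nrow(combo) == 0) stop("no combination rows (both concentrations > 0)")
  resid_fn <- function(theta) {
    p <- interaction_params(drug_a, drug_b, psi = theta[["psi"]], r0 = r0,
                            psi_on = psi_on)
    pred <- competitive_interaction_response(p, combo$conc_a, combo$conc_b)
    .weight_resid(combo$viability, pred, weighting)
  }
  sets <- lapply(c(0.1, 0.5, 1, 2, 10), function(v) c(psi = v))
  b <- .bounds_for("psi", fit_spec(free = "psi"))
  fit <- .ls_fit(resid_fn, sets, list(), b$lower, b$upper)
  .make_fit_result(fit, "psi", list(), nrow(combo), "interaction_static")
}

# Vectorised closed-form prediction for a single agent (no interaction).
.pd_single_pred <- function(theta, conc, time) {
  k <- theta[["smax"]] * conc / (theta[["sc50"]] + conc)
  theta[["r0"]] * exp(theta[["kg"]] * time - .k3_auc(k, theta[["tau"]], time))
}

#' Fit the single-agent cell-kill PD model to time-course data
#'
#' Simultaneous least squares over all treatment arms (control plus drug
#' concentrations) of one drug's time courses against the transit-compartment
#' kill model. Arms are simulated with the exact constant-exposure solution
#' of the model (see [simulate_pd()]). By default `kg`, `smax`, `sc50` and
#' `tau` are estimated jointly with `r0 = 100` fixed; a control arm
#' (`conc == 0`) must be present unless `kg` is fixed.
#'
#' Multi-start protection: five log-spaced `sc50` starts spanning 0.01x to
#' 100x the highest tested concentration, crossed with three transit-time
#' starts.
#'
#' @param data `data.frame` with columns `conc` (uM), `time` (h) and
#'   `viability` (%).
#' @param spec A [fit_spec()] over `{kg, r0, smax, sc50, tau}`.
#' @return A `fit_result`.
#' @export
fit_pd_single <- function(data,
                          spec = fit_spec(free = c("kg", "smax", "sc50", "tau"),
                                          fixed = list(r0 = 100))) {
  stopifnot(all(c("conc", "time", "viability") %in% names(data)))
  .check_spec_complete(spec, c("kg", "r0", "smax", "sc50", "tau"))
  if ("kg" %in% spec$free && !any(data$conc == 0)) {
    stop("kg is free but no control arm (conc == 0) is present")
  }
  obs <- data$viability
  resid_fn <- function(theta) {
    .weight_resid(obs, .pd_single_pred(theta, data$conc, data$time),
                  spec$weighting)
  }
  ctrl <- data[data$conc == 0 & data$time > 0 & data$viability > 0, ]
  kg0 <- if (nrow(ctrl) >= 2) {
    max(1e-4, stats::coef(stats::lm(log(viability) ~ time, data = ctrl))[2])
  } else 0.01
  cmax <- max(data$conc)
  base <- .merge_start(list(kg = kg0, r0 = 100, smax = 0.05,
                            sc50 = cmax, tau = 1), spec)[spec$free]
  multi <- list()
  if ("sc50" %in% spec$free && is.null(spec$start$sc50)) {
    multi$sc50 <- cmax * 10^seq(-2, 2)
  }
  if ("tau" %in% spec$free && is.null(spec$start$tau)) {
    multi$tau <- c(0.5, 2, 10)
  }
  b <- .bounds_for(spec$free, spec)
  fit <- .ls_fit(resid_fn, .start_sets(base, multi), spec$fixed,
                 b$lower, b$upper)
  .make_fit_result(fit, spec$free, spec$fixed, nrow(data), "pd_single")
}

# Vectorised closed-form combination prediction; psi scales SC50 of drug A
# (cisplatin) only.
.pd_combo_pred <- function(params, psi, conc_a, conc_b, time) {
  ka <- params$cis$smax * conc_a / (params$cis$sc50 * psi + conc_a)
  kb <- params$cim$smax * conc_b / (params$cim$sc50 + conc_b)
  params$r0 * exp(params$kg * time -
                    .k3_auc(ka, params$cis$tau, time) -
                    .k3_auc(kb, params$cim$tau, time))
}

#' Estimate the time-course interaction parameter psi
#'
#' Fits the combination PD model to combination time courses with every
#' single-agent parameter fixed (growth rate, both drugs' kill parameters
#' and baseline), estimating only the interaction parameter psi that scales
#' the cisplatin SC50. This mirrors the sequential estimate-then-fix
#' workflow used for the single agents.
#'
#' @param data `data.frame` with columns `conc_a` (cisplatin, uM), `conc_b`
#'   (cimetidine, uM), `time` (h) and `viability` (%); rows with both
#'   concentrations > 0 are the combination arms (at least one required).
#' @param params A [pd_system_params()] with the fixed single-agent values
#'   (its `psi` field is ignored).
#' @param weighting Residual weighting, as in [fit_spec()].
#' @return A `fit_result` with the psi estimate.
#' @export
fit_pd_combo <- function(data, params,
                         weighting = c("none", "proportional")) {
  stopifnot(all(c("conc_a", "conc_b", "time", "viability") %in% names(data)),
            inherits(params, "pd_system_params"))
  weighting <- match.arg(weighting)
  combo <- data[data$conc_a > 0 & data$conc_b > 0, , drop = FALSE]
  if (nrow(combo) == 0) stop("no combination rows (both concentrations > 0)")
  resid_fn <- function(theta) {
    pred <- .pd_combo_pred(params, theta[["psi"]], combo$conc_a,
                           combo$conc_b, combo$time)
    .weight_resid(combo$viability, pred, weighting)
  }
  sets <- lapply(c(0.1, 0.5, 1, 2, 10), function(v) c(psi = v))
  b <- .bounds_for("psi", fit_spec(free = "psi"))
  fit <- .ls_fit(resid_fn, sets, list(), b$lower, b$upper)
  .make_fit_result(fit, "psi", list(), nrow(combo), "pd_combo")
}
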