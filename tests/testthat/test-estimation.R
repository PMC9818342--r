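test_that("noise-free Hill data are fit back to the generating parameters", {
  concs <- exp(seq(log(0.05), log(25), length.out = 6))
  truth <- reference_hill("Huh7", "CIS")
  fit <- fit_hill(hill_dataset(truth, concs))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["ic50"]), truth$ic50, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["imax"]), truth$imax, tolerance = 1e-4)

  # all-free fit (the cimetidine pattern), steep curve
  cim_concs <- exp(seq(log(50), log(4000), length.out = 6))
  truth_cim <- reference_hill("Huh7", "CIM")
  fit_cim <- fit_hill(hill_dataset(truth_cim, cim_concs),
                      fit_spec(free = c("r0", "imax", "ic50", "gamma")))
  expect_equal(unname(fit_cim$estimates["gamma"]), 3.12, tolerance = 1e-3)
  expect_equal(unname(fit_cim$estimates["ic50"]), 3190, tolerance = 1e-3)

  # property: randomized truths round-trip through the fitter
  set.seed(21)
  for (i in 1:10) {
    p <- random_hill()
    cc <- p$ic50 * 10^seq(-2, 2, length.out = 8)
    f <- fit_hill(hill_dataset(p, cc),
                  fit_spec(free = c("imax", "ic50", "gamma"),
                           fixed = list(r0 = p$r0)))
    expect_equal(unname(f$estimates["ic50"]), p$ic50, tolerance = 1e-3)
    expect_equal(unname(f$estimates["gamma"]), p$gamma, tolerance = 1e-3)
  }
})

test_that("degenerate concentration-response data are handled as specified", {
  concs <- c(0.1, 1, 10, 100)
  flat <- data.frame(conc = concs, viability = rep(100, 4))
  expect_error(fit_hill(flat, fit_spec(free = c("r0", "imax", "ic50"),
                                       fixed = list(gamma = 1))),
               "degenerate")
  # with r0 fixed the fit runs and parks imax at its lower boundary
  f <- fit_hill(flat)
  expect_lt(unname(f$estimates["imax"]), 1e-4)
  expect_true("imax" %in% f$boundary)
  expect_error(fit_hill(data.frame(conc = c(1, 2), viability = c(90, 80))),
               "4 distinct")
})

test_that("static psi is recovered from noise-free combination grids", {
  for (truth_psi in c(0.95, 1, 1.27)) {
    ip <- huh7_static_truth(psi = truth_psi)
    grid <- generate_static(default_design("Huh7"), ip, nf)
    fit <- fit_interaction_static(as_combination(grid, 72),
                                  ip$drug_a, ip$drug_b)
    expect_equal(unname(fit$estimates["psi"]), truth_psi, tolerance = 1e-4)
  }
  expect_error(fit_interaction_static(
    data.frame(conc_a = c(1, 0), conc_b = c(0, 5), viability = c(50, 60)),
    reference_hill("Huh7", "CIS"), reference_hill("Huh7", "CIM")),
    "combination")
})

test_that("single-agent PD fits recover the generating kill parameters", {
  des <- default_design("Huh7")
  truth <- reference_pd("Huh7")
  tc <- generate_timecourse(des, truth, nf)
  fit <- fit_pd_single(as_single_agent(tc, "CIS"))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["kg"]), truth$kg, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["smax"]), truth$cis$smax, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["sc50"]), truth$cis$sc50, tolerance = 1e-3)
  expect_equal(1 / unname(fit$estimates["tau"]), 1.17, tolerance = 1e-3)

  # cimetidine in MDA-MB-468: SC50 far above the tested range
  des2 <- default_design("MDA-MB-468")
  truth2 <- reference_pd("MDA-MB-468")
  tc2 <- generate_timecourse(des2, truth2, nf)
  fit2 <- fit_pd_single(as_single_agent(tc2, "CIM"),
                        fit_spec(free = c("smax", "sc50", "tau"),
                                 fixed = list(r0 = 100, kg = truth2$kg)))
  expect_equal(unname(fit2$estimates["sc50"]), 21453.95, tolerance = 1e-3)

  # zero drug effect: smax collapses to its lower boundary, kg still right
  no_kill <- truth
  no_kill$cis$smax <- 1e-6
  tc0 <- generate_timecourse(des, no_kill, nf)
  fit0 <- fit_pd_single(as_single_agent(tc0, "CIS"))
  expect_lt(unname(fit0$estimates["smax"]), 1e-4)
  expect_equal(unname(fit0$estimates["kg"]), truth$kg, tolerance = 1e-3)

  expect_error(fit_pd_single(as_combination(tc)[0, ]), "conc")
  no_ctrl <- as_single_agent(tc, "CIS")
  expect_error(fit_pd_single(no_ctrl[no_ctrl$conc > 0, ]), "control")
})

test_that("time-course psi is recovered with single-agent parameters fixed", {
  des <- default_design("Huh7")
  for (truth_psi in c(0.96, 1)) {
    truth <- reference_pd("Huh7", psi = truth_psi)
    tc <- generate_timecourse(des, truth, nf)
    fit <- fit_pd_combo(as_combination(tc), truth)
    expect_equal(unname(fit$estimates["psi"]), truth_psi, tolerance = 1e-3)
  }
})

test_that("fixing a parameter at its truth does not worsen recovery", {
  concs <- exp(seq(log(0.05), log(25), length.out = 6))
  truth <- hill_params(r0 = 100, imax = 0.9, ic50 = 2.5, gamma = 1.4)
  d <- hill_dataset(truth, concs)
  free_fit <- fit_hill(d, fit_spec(free = c("imax", "ic50", "gamma"),
                                   fixed = list(r0 = 100)))
  fixed_fit <- fit_hill(d, fit_spec(free = c("imax", "ic50"),
                                    fixed = list(r0 = 100, gamma = truth$gamma)))
  err_free <- abs(free_fit$estimates["ic50"] - truth$ic50)
  err_fixed <- abs(fixed_fit$estimates["ic50"] - truth$ic50)
  expect_lte(err_fixed, err_free + 1e-8)
})

test_that("accepted optimizer steps decrease the objective monotonically", {
  set.seed(22)
  ip <- huh7_static_truth()
  grid <- generate_static(default_design("Huh7"), ip, noise_model(0.1, 2, 7))
  fit <- fit_interaction_static(as_combination(grid, 72),
                                ip$drug_a, ip$drug_b)
  expect_true(all(diff(fit$rss_trace) <= 1e-8))
})

test_that("relative standard errors behave like least-squares theory says", {
  # noise-free fit: RSE collapses to ~0
  ip <- huh7_static_truth()
  grid <- generate_static(default_design("Huh7"), ip, nf)
  fit <- fit_interaction_static(as_combination(grid, 72),
                                ip$drug_a, ip$drug_b)
  expect_lt(fit$rse_pct["psi"], 1e-3)

  # single-parameter toy problem: estimate and SE match stats::nls as an
  # independent oracle (delta-method SE from the log-scale fit agrees to
  # first order)
  set.seed(23)
  x <- 1:12
  yexp <- 100 * exp(0.02 * x) * (1 + rnorm(12, 0, 0.05))
  fitg <- fit_growth(data.frame(time = x, viability = yexp))
  nls_ref <- stats::nls(v ~ 100 * exp(k * t),
                        data = data.frame(t = x, v = yexp),
                        start = list(k = 0.02))
  expect_equal(unname(fitg$estimates["kg"]),
               unname(stats::coef(nls_ref)["k"]), tolerance = 1e-6)
  expect_equal(unname(fitg$se["kg"]),
               unname(summary(nls_ref)$coefficients["k", "Std. Error"]),
               tolerance = 0.02)

  # RSE shrinks roughly as 1/sqrt(n) when replication increases 16-fold
  des_small <- default_design("Huh7")
  des_big <- des_small
  des_big$replicates <- 48
  g_small <- generate_static(des_small, ip, noise_model(0.1, 0, 31))
  g_big <- generate_static(des_big, ip, noise_model(0.1, 0, 32))
  r_small <- fit_interaction_static(as_combination(g_small, 72),
                                    ip$drug_a, ip$drug_b)$rse_pct["psi"]
  r_big <- fit_interaction_static(as_combination(g_big, 72),
                                  ip$drug_a, ip$drug_b)$rse_pct["psi"]
  expect_gt(r_small / r_big, 2.5)
  expect_lt(r_small / r_big, 6.5)
})

test_that("fit_spec rejects inconsistent specifications", {
  expect_error(fit_spec(free = "ic50", fixed = list(ic50 = 1)), "disjoint")
  expect_error(fit_hill(hill_dataset(reference_hill("Huh7", "CIS"),
                                     c(0.1, 1, 5, 20)),
                        fit_spec(free = "ic50", fixed = list(r0 = 100))),
               "cover")
  expect_error(fit_hill(hill_dataset(reference_hill("Huh7", "CIS"),
                                     c(0.1, 1, 5, 20)),
                        fit_spec(free = c("ic50", "zeta"),
                                 fixed = list(r0 = 100, imax = 1, gamma = 1))),
               "unknown")
})
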