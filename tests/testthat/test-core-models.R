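test_that("Hill response honours zero-dose, half-maximal and scalar identities", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_hill()
    expect_equal(hill_response(p, 0), p$r0)
    # at conc = ic50 inhibition is imax/2 regardless of gamma
    expect_equal(hill_response(p, p$ic50), p$r0 * (1 - p$imax / 2))
  }
  p <- hill_params(r0 = 100, imax = 1, ic50 = 1.96, gamma = 1)
  expect_equal(hill_response(p, 25), 100 * (1 - 25 / 26.96), tolerance = 1e-12)
  expect_equal(hill_response(p, 25), 7.2700297, tolerance = 1e-6)
  expect_error(hill_response(p, -1), "concentration")
})

test_that("Hill and interaction responses are non-increasing in concentration", {
  # the Hill curve is monotone for any parameters; the competitive
  # interaction response is monotone in each dose when the drugs share Imax
  # (raising one dose can otherwise displace a more efficacious competitor),
  # so draws are constrained to equal Imax and the published sets are
  # checked separately
  set.seed(12)
  cgrid <- c(0, 10^seq(-3, 4, length.out = 40))
  for (i in 1:20) {
    p <- random_hill()
    expect_true(all(diff(hill_response(p, cgrid)) <= 1e-12))
    a <- random_hill()
    b <- random_hill()
    b$imax <- a$imax
    ip <- interaction_params(a, b, psi = 10^runif(1, -1, 1))
    fix_b <- 10^runif(1, -1, 3)
    expect_true(all(diff(competitive_interaction_response(ip, cgrid, fix_b)) <= 1e-9))
    expect_true(all(diff(competitive_interaction_response(ip, fix_b, cgrid)) <= 1e-9))
  }
  for (cl in c("Huh7", "MDA-MB-468")) {
    ip <- interaction_params(reference_hill(cl, "CIS"),
                             reference_hill(cl, "CIM"), psi = 1)
    expect_true(all(diff(competitive_interaction_response(ip, cgrid, 500)) <= 1e-9))
    expect_true(all(diff(competitive_interaction_response(ip, 5, cgrid)) <= 1e-9))
  }
})

test_that("interaction model reduces correctly at zero doses and single-drug limits", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_hill(); b <- random_hill()
    psi <- 10^runif(1, -1, 1)
    ip <- interaction_params(a, b, psi = psi, r0 = 100)
    expect_equal(competitive_interaction_response(ip, 0, 0), 100)
    # with drug B absent: Hill curve of A with ic50 -> psi * ic50
    conc <- 10^seq(-2, 3, length.out = 9)
    shifted <- hill_params(r0 = 100, imax = a$imax, ic50 = psi * a$ic50,
                           gamma = a$gamma)
    expect_equal(competitive_interaction_response(ip, conc, 0),
                 hill_response(shifted, conc), tolerance = 1e-12)
    # psi_on = "a" leaves drug B's axis unscaled
    ipa <- interaction_params(a, b, psi = psi, r0 = 100, psi_on = "a")
    unshifted_b <- hill_params(r0 = 100, imax = b$imax, ic50 = b$ic50,
                               gamma = b$gamma)
    expect_equal(competitive_interaction_response(ipa, 0, conc),
                 hill_response(unshifted_b, conc), tolerance = 1e-12)
  }
  # closed-form check: equipotent doses, full inhibition, psi = 1 -> 1 - 2/3
  a <- hill_params(100, 1, 2, 1.5); b <- hill_params(100, 1, 700, 0.8)
  ip <- interaction_params(a, b, psi = 1)
  expect_equal(competitive_interaction_response(ip, 2, 700), 100 / 3,
               tolerance = 1e-12)
})

test_that("interaction response is non-decreasing in psi at fixed positive doses", {
  # guaranteed when the two drugs share Imax (total inhibition is then
  # Imax * s/(s+1) with s = x + y decreasing in psi); with unequal Imax and
  # Hill slopes the surface can cross, so the property is asserted for
  # equal-Imax draws and, separately, at the published parameter sets
  set.seed(14)
  psis <- c(0.1, 0.3, 1, 3, 10)
  for (i in 1:20) {
    a <- random_hill()
    b <- random_hill()
    b$imax <- a$imax
    ca <- 10^runif(1, -1, 2); cb <- 10^runif(1, 1, 3.5)
    r <- vapply(psis, function(ps) {
      competitive_interaction_response(interaction_params(a, b, psi = ps),
                                       ca, cb)
    }, numeric(1))
    expect_true(all(diff(r) >= -1e-9))
  }
  for (cl in c("Huh7", "MDA-MB-468")) {
    a <- reference_hill(cl, "CIS"); b <- reference_hill(cl, "CIM")
    for (doses in list(c(1, 500), c(25, 4000), c(0.05, 50))) {
      r <- vapply(psis, function(ps) {
        competitive_interaction_response(interaction_params(a, b, psi = ps),
                                         doses[1], doses[2])
      }, numeric(1))
      expect_true(all(diff(r) >= -1e-9))
    }
  }
})

test_that("control growth follows the exponential solution", {
  ctrl <- simulate_control(kg = 0.011, r0 = 100, times = c(0, 24, 48, 72, 96))
  expect_equal(ctrl$viability_pct[1], 100)
  expect_equal(ctrl$viability_pct[5], 100 * exp(0.011 * 96), tolerance = 1e-12)
  expect_equal(ctrl$viability_pct[5], 287.4849, tolerance = 1e-6)
  expect_equal(simulate_control(0, 100, c(0, 48, 96))$viability_pct,
               rep(100, 3))
  expect_error(simulate_control(0.01, 100, c(48, 0, 96)), "ascending")
})

test_that("constant-input transit chain matches an independent ODE integration", {
  expect_equal(transit_k3_closed_form(0.1, 1, 0), 0)
  expect_equal(transit_k3_closed_form(0.1, 1, 1), 0.1 * (1 - exp(-1) * 2.5),
               tolerance = 1e-12)
  expect_equal(transit_k3_closed_form(0.1, 1, 1), 0.00803014, tolerance = 1e-6)
  # steady state is the input rate
  expect_equal(transit_k3_closed_form(0.07, 2, 1e4), 0.07, tolerance = 1e-9)
  expect_error(transit_k3_closed_form(0.1, 0, 1), "tau")
  # oracle: integrate the three-stage chain directly with deSolve
  k <- 0.085; tau <- 3.2
  chain <- function(t, y, parms) {
    list(c((k - y[1]) / tau, (y[1] - y[2]) / tau, (y[2] - y[3]) / tau))
  }
  tt <- c(0, 1, 2, 5, 10, 25, 60)
  num <- deSolve::ode(c(0, 0, 0), tt, chain, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(transit_k3_closed_form(k, tau, tt), unname(num[, 4]),
               tolerance = 1e-7)
})

test_that("PD simulation: initial condition, zero-dose and psi = 1 reductions", {
  p <- reference_pd("Huh7")
  tt <- c(0, 12, 24, 48, 72, 96)
  # zero dose reproduces the control model exactly
  for (m in c("ode", "closed_form")) {
    z <- simulate_pd(p, exposure_spec(0, 0), tt, method = m)
    expect_equal(z$viability_pct, simulate_control(p$kg, p$r0, tt)$viability_pct,
                 tolerance = 1e-8)
    expect_equal(z$viability_pct[1], p$r0, tolerance = 1e-10)
  }
  # psi = 1 combination system with CIM absent equals the single-agent system
  p1 <- reference_pd("Huh7", psi = 1)
  combo <- simulate_pd(p1, exposure_spec(5, 0), tt, method = "ode")
  single <- local({
    # single-agent trajectory via the closed-form solution with only CIS
    k <- p1$cis$smax * 5 / (p1$cis$sc50 + 5)
    u <- tt / p1$cis$tau
    p1$r0 * exp(p1$kg * tt - k * (tt - 3 * p1$cis$tau +
      p1$cis$tau * exp(-u) * (3 + 2 * u + u^2 / 2)))
  })
  expect_equal(combo$viability_pct, single, tolerance = 1e-7)
  expect_error(simulate_pd(p, exposure_spec(5, 0, t_end = 48), tt), "t_end")
})

test_that("ODE and closed-form trajectories agree across random parameter draws", {
  set.seed(15)
  tt <- c(0, 6, 24, 48, 96)
  for (i in 1:100) {
    p <- random_pd_system(psi = 10^runif(1, -1, 1))
    ex <- exposure_spec(conc_cis = 10^runif(1, -2, 1.5),
                        conc_cim = 10^runif(1, 1, 3.6))
    a <- simulate_pd(p, ex, tt, method = "ode")$viability_pct
    b <- simulate_pd(p, ex, tt, method = "closed_form")$viability_pct
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("terminal viability under combination is non-decreasing in psi", {
  set.seed(16)
  for (i in 1:15) {
    base <- random_pd_system()
    ca <- 10^runif(1, -1, 0.5); cb <- 10^runif(1, 1.5, 3.5)
    term <- vapply(c(0.2, 0.5, 1, 2, 5), function(ps) {
      p <- base; p$psi <- ps
      simulate_pd(p, exposure_spec(ca, cb), c(0, 96),
                  method = "closed_form")$viability_pct[2]
    }, numeric(1))
    expect_true(all(diff(term) >= -1e-9))
  }
})

test_that("parameter containers validate their invariants", {
  expect_error(hill_params(100, 1.2, 1, 1), "imax")
  expect_error(hill_params(100, 1, -1, 1), "ic50")
  expect_error(pd_agent_params(0, 1, 1), "smax")
  expect_error(pd_system_params(kg = 0.01, cis = pd_agent_params(1, 1, 1),
                                cim = pd_agent_params(1, 1, 1), psi = 0),
               "psi")
  expect_error(exposure_spec(-1, 0), "concentrations")
})
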