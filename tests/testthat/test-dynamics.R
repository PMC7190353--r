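sp <- spectrin_species()

test_that("spectrin defaults carry the literature parameter values", {
  expect_equal(sp$ell_u, 1200)
  expect_equal(sp$ell_f, 200)
  expect_equal(sp$ell0p, 170)
  expect_equal(sp$nu_f0 / sp$nu_u0, 1e7)
  expect_equal(sp$wlc$persistence_length, 20)
  expect_equal(sp$wlc$kBT, 4)
  expect_error(crosslinker_species("bad", ell_f = 300, ell_u = 200,
                                   ell0p = 100, dx_fu = 1, dx_uf = 1,
                                   nu_u0 = 1, nu_f0 = 1),
               "ell_f < ell_u")
})

test_that("Bell rates respond exponentially to tension", {
  r0 <- transition_rates(0, sp)
  expect_equal(r0$nu_u, 1e-5)
  expect_equal(r0$nu_f, 100)
  # direct evaluation: beta*T = 1 at T = 4 pN, kBT = 4
  r4 <- transition_rates(4, sp)
  expect_equal(r4$nu_u, 1e-5 * exp(2.5), tolerance = 1e-12)
  expect_equal(r4$nu_f, 100 * exp(-15), tolerance = 1e-12)
  # monotone in T
  Ts <- seq(0, 20, by = 2)
  r <- transition_rates(Ts, sp)
  expect_true(all(diff(r$nu_u) > 0))
  expect_true(all(diff(r$nu_f) < 0))
  expect_error(transition_rates(-1, sp), "non-negative")
  # zero reaction-coordinate lengths: rates independent of tension
  s0 <- crosslinker_species("flat", 200, 1200, 170, 0, 0, 1e-5, 100)
  rf <- transition_rates(c(0, 10), s0)
  expect_equal(rf$nu_u, c(1e-5, 1e-5))
  expect_equal(rf$nu_f, c(100, 100))
})

test_that("rest-length rate composes rates and element tension", {
  # fully unfolded: pure refolding drive
  expect_equal(rest_length_rate(sp$ell_u, 1, sp),
               -transition_rates(element_tension(1, sp$ell_u, 170), sp)$nu_f *
                 (sp$ell_u - sp$ell_f))
  expect_lt(rest_length_rate(sp$ell_u, 1, sp), 0)
  # fully folded with negligible unfolding: no drift
  s_slow <- crosslinker_species("slow", 200, 1200, 170, 0, 15, 1e-30, 100)
  expect_equal(rest_length_rate(200, 1, s_slow), 1e-30 * 1000,
               tolerance = 1e-12)
  # composition oracle at ell = 200, lambda = 1
  T <- oracle_wlc(0.85)
  nu_u <- 1e-5 * exp(T * 2.5 / 4)
  expect_equal(rest_length_rate(200, 1, sp), nu_u * 1000, tolerance = 1e-12)
})

test_that("steady-state rest length solves the self-consistency relation", {
  # tension-independent symmetric rates: exact midpoint
  s_sym <- crosslinker_species("sym", 200, 1200, 170, 0, 0, 2, 2)
  expect_equal(as.numeric(steady_state_rest_length(1, s_sym)), 700)
  # refolding-dominated limit collapses to the folded length (clamped)
  s_fold <- crosslinker_species("fold", 200, 1200, 170, 0, 0, 1e-30, 100)
  lss_f <- steady_state_rest_length(1, s_fold)
  expect_equal(as.numeric(lss_f), 200, tolerance = 1e-6)
  # spectrin defaults: matches an independent bisection oracle, tiny residual
  lss <- steady_state_rest_length(1, sp)
  expect_equal(as.numeric(lss), oracle_ss_rest_length(1, sp), tolerance = 1e-8)
  r <- transition_rates(element_tension(1, as.numeric(lss), 170), sp)
  resid <- as.numeric(lss) -
    (r$nu_u * sp$ell_u + r$nu_f * sp$ell_f) / (r$nu_u + r$nu_f)
  expect_lt(abs(resid), 1e-9)
  # nondecreasing in deformation
  lams <- 1 + seq(0, 0.3, by = 0.05)
  lsss <- vapply(lams, function(l) as.numeric(steady_state_rest_length(l, sp)),
                 numeric(1))
  expect_true(all(diff(lsss) >= 0))
  expect_error(steady_state_rest_length(1200 / 170, sp),
               "fully unfolded length")
})

test_that("steady-state tension curve is pre-tensed, linear in n, softening", {
  m <- axon_model(sp)
  curve <- steady_state_tension_curve(seq(0, 0.2, by = 0.02), m)
  expect_gt(curve$tension_nN[1], 0) # under tension at zero strain
  expect_true(all(diff(curve$ell_ss_spectrin) > 0)) # unfolding with strain
  # doubling the copy number doubles the tension everywhere
  m2 <- axon_model(spectrin_species(n = 2))
  curve2 <- steady_state_tension_curve(seq(0, 0.2, by = 0.02), m2)
  expect_equal(curve2$tension_nN, 2 * curve$tension_nN, tolerance = 1e-12)
  # zero-strain value equals the composed oracle
  lss0 <- oracle_ss_rest_length(1, sp)
  expect_equal(curve$tension_nN[1], oracle_wlc(170 / lss0) / 1000,
               tolerance = 1e-7)
})

test_that("two parallel species add their tensions independently", {
  tau_like <- crosslinker_species("tau", ell_f = 80, ell_u = 400, ell0p = 60,
                                  dx_fu = 1, dx_uf = 5, nu_u0 = 1e-4,
                                  nu_f0 = 10, n = 50)
  m_both <- axon_model(list(spectrin_species(n = 300), tau_like))
  g <- c(0, 0.1)
  both <- steady_state_tension_curve(g, m_both)
  one <- steady_state_tension_curve(g, axon_model(spectrin_species(n = 300)))
  two <- steady_state_tension_curve(g, axon_model(tau_like))
  expect_equal(both$tension_nN, one$tension_nN + two$tension_nN,
               tolerance = 1e-12)
})

test_that("analytic relaxation time reduces to the constant-rate limit", {
  s0 <- crosslinker_species("flat", 200, 1200, 170, 0, 0, 0.3, 0.7)
  expect_equal(relaxation_time_analytic(1, s0), 1 / (0.3 + 0.7),
               tolerance = 1e-12)
  expect_equal(relaxation_time_numeric(1, s0), 1 / (0.3 + 0.7),
               tolerance = 1e-3)
})

test_that("at small strain refolding dominates and sets the timescale", {
  lss <- as.numeric(steady_state_rest_length(1, sp))
  r <- transition_rates(element_tension(1, lss, 170), sp)
  expect_lt(r$nu_u / r$nu_f, 1e-2)
  tau <- relaxation_time_analytic(1, sp)
  # same order as 1/nu_f; the stiffness correction shortens it further
  expect_lt(tau, 1 / r$nu_f)
  expect_gt(tau * r$nu_f, 0.2)
})

test_that("numeric relaxation oracle agrees with the analytic expression", {
  for (g in c(0, 0.05, 0.15)) {
    ta <- relaxation_time_analytic(1 + g, sp)
    tn <- relaxation_time_numeric(1 + g, sp)
    expect_lt(abs(tn - ta) / ta, 0.02)
  }
  # linear-regime consistency: halving the increment barely moves the fit
  t1 <- relaxation_time_numeric(1.05, sp, delta_gamma = 2e-4)
  t2 <- relaxation_time_numeric(1.05, sp, delta_gamma = 1e-4)
  expect_lt(abs(t2 - t1) / t1, 0.005)
})

test_that("protocol simulation holds steady states and conserves bounds", {
  m <- axon_model(sp)
  # no steps: tension stays at the zero-strain steady state
  flat <- simulate_protocol(m, strain_protocol(numeric(0), numeric(0), 100),
                            n_per_segment = 60)
  expect_lt(diff(range(flat$tension_nN)) / flat$tension_nN[1], 1e-6)
  # single small step, long wait: endpoint on the steady-state curve
  tau <- relaxation_time_analytic(1.05, sp)
  one <- simulate_protocol(m, strain_protocol(0, 0.05, end_time = 8 * tau),
                           n_per_segment = 120)
  Tss <- steady_state_tension_curve(0.05, m)$tension_nN
  expect_lt(abs(utils::tail(one$tension_nN, 1) - Tss) / Tss, 0.01)
  # tension jumps at the step then relaxes monotonically
  expect_gt(one$tension_nN[1], Tss)
  expect_true(all(diff(one$tension_nN) < 1e-12))
  # rest length confined to [ell_f, ell_u]
  expect_true(all(one$ell_spectrin >= sp$ell_f - 1e-9))
  expect_true(all(one$ell_spectrin <= sp$ell_u + 1e-9))
})

test_that("up-down cycling returns the element to its initial state", {
  m <- axon_model(sp)
  tau_up <- relaxation_time_analytic(1.1, sp)
  tau_dn <- relaxation_time_analytic(1, sp)
  pr <- strain_protocol(c(0, 10 * tau_up), c(0.1, 0),
                        end_time = 10 * tau_up + 10 * tau_dn)
  tr <- simulate_protocol(m, pr, n_per_segment = 120)
  ell0 <- as.numeric(steady_state_rest_length(1, sp))
  expect_lt(abs(utils::tail(tr$ell_spectrin, 1) - ell0) / ell0, 0.01)
})

test_that("overstretching protocols fail loudly with the species name", {
  m <- axon_model(sp)
  # lambda * ell0p >= ell_u can never relax: 1200/170 - 1 = 6.06 strain
  expect_error(
    simulate_protocol(m, strain_protocol(0, 6.5, end_time = 10)),
    "spectrin")
  expect_error(strain_protocol(c(0, 0), c(0.1, 0.2), 10),
               "strictly increasing")
  expect_error(strain_protocol(0, -0.1, 10), "non-negative")
})
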