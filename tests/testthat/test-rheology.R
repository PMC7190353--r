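test_that("pulling geometry formulas match their closed forms", {
  # strain from mid-point displacement
  expect_equal(strain_from_displacement(0, 100), 0)
  expect_equal(strain_from_displacement(50, 100), sqrt(2) - 1)
  # quadratic onset: gamma ~ 2 d^2 / L0^2
  d <- 0.1
  expect_equal(strain_from_displacement(d, 100), 2 * d^2 / 100^2,
               tolerance = 1e-6)
  expect_error(strain_from_displacement(-1, 100), "non-negative")
  # cantilever force
  expect_equal(cantilever_force(10, 10, 0.1), 0)
  expect_equal(cantilever_force(20, 10, 0.1), 1)
  expect_equal(cantilever_force(20, 10, 0.2), 2)
  expect_error(cantilever_force(5, 10, 0.1), "D < d")
  # axial tension from the force triangle
  expect_equal(axial_tension(1, 50, 100), 1 / sqrt(2))
  expect_equal(axial_tension(0, 50, 100), 0)
  expect_equal(axial_tension(1, 1e6, 100), 0.5, tolerance = 1e-6)
  expect_error(axial_tension(1, 0, 100), "singular geometry")
})

test_that("force balance 2 T sin(theta) = F holds on every processed sample", {
  set.seed(4)
  g <- default_geometry()
  d <- sort(runif(50, 1, 40))
  t <- seq_along(d)
  D <- d + runif(50, 0.1, 20)
  tr <- record_to_trace(force_record(t, D, d, g))
  sin_theta <- d / sqrt(d^2 + (g$L0 / 2)^2)
  expect_equal(2 * tr$tension_nN * sin_theta, tr$F_nN, tolerance = 1e-12)
})

test_that("zero-deflection samples are dropped with a warning", {
  g <- default_geometry()
  rec <- force_record(1:4, c(0, 1, 2, 3), c(0, 1, 2, 3), g)
  expect_warning(tr <- record_to_trace(rec), "d = 0")
  expect_equal(nrow(tr), 3)
})

test_that("step windows are recovered from generator metadata", {
  m <- axon_model(spectrin_species(n = 300))
  g <- default_geometry()
  pr <- default_step_protocol(m)
  rec <- generate_force_record(m, pr, g)
  tr <- record_to_trace(rec)
  st <- segment_steps(tr)
  expect_equal(nrow(st), 4)
  expect_equal(st$t_step, pr$step_times, tolerance = 0.05)
  expect_equal(st$gamma_after, pr$strains, tolerance = 1e-6)
  # constant-strain trace: no windows
  flat <- data.frame(t = 1:100, gamma = 0.05, tension_nN = 1)
  expect_equal(nrow(segment_steps(flat)), 0)
  # cyclic protocol: alternating target strains
  tau <- relaxation_time_analytic(1.01, spectrin_species())
  cyc <- strain_protocol(seq(0, by = 6 * tau, length.out = 4),
                         c(0.01, 0.002, 0.01, 0.002),
                         end_time = 24 * tau)
  rec_c <- generate_force_record(m, cyc, g)
  st_c <- segment_steps(record_to_trace(rec_c), threshold = 0.002)
  expect_equal(st_c$gamma_after, c(0.01, 0.002, 0.01, 0.002),
               tolerance = 1e-3)
})

test_that("steady-state tension estimator is unbiased within its noise bound", {
  # constant signal returns the constant
  flat <- data.frame(t = seq(0, 10, length.out = 100), gamma = 0.1,
                     tension_nN = 3)
  w <- list(i_start = 1L, i_end = 100L)
  expect_equal(as.numeric(steady_state_tension(flat, w)), 3)
  expect_false(attr(steady_state_tension(flat, w), "nonstationary"))
  # additive noise: within 3 sigma/sqrt(m) of truth in seeded replicates
  set.seed(9)
  sig <- 0.2
  errs <- replicate(30, {
    y <- 5 + rnorm(200, 0, sig)
    df <- data.frame(t = seq(0, 10, length.out = 200), gamma = 0.1,
                     tension_nN = y)
    m_tail <- sum(df$t >= 9) # tail_fraction 0.1 of the span
    abs(as.numeric(steady_state_tension(df, list(i_start = 1L, i_end = 200L))) - 5) <
      3 * sig / sqrt(m_tail)
  })
  expect_gte(mean(errs), 0.9)
  expect_error(steady_state_tension(flat, list(i_start = 1L, i_end = 5L)),
               "too short")
  # drifting tail is flagged
  drift <- data.frame(t = seq(0, 10, length.out = 200), gamma = 0.1,
                      tension_nN = seq(5, 4, length.out = 200))
  expect_true(attr(steady_state_tension(drift, list(i_start = 1L, i_end = 200L)),
                   "nonstationary"))
})

test_that("rest tension extrapolation recovers a linear intercept", {
  g <- c(0.01, 0.03, 0.05, 0.2)
  expect_equal(rest_tension_extrapolate(g, 2 + 7 * g), 2, tolerance = 1e-10)
  expect_error(rest_tension_extrapolate(0.1, 5), "at least 2")
  # model-generated small-strain pairs bracket the true rest tension
  m <- axon_model(spectrin_species())
  gs <- c(0.01, 0.03, 0.05)
  curve <- steady_state_tension_curve(c(0, gs), m)
  T0 <- rest_tension_extrapolate(gs, curve$tension_nN[-1])
  expect_lt(abs(T0 - curve$tension_nN[1]) / curve$tension_nN[1], 0.05)
})

test_that("effective Young's modulus arithmetic and units", {
  expect_equal(youngs_modulus(1.5, 0.5, pi * 0.5^2, 0.1),
               1 / (pi * 0.25 * 0.1), tolerance = 1e-12) # ~12.73 kPa
  expect_equal(youngs_modulus(2, 2, 1, 0.1), 0)
  expect_equal(youngs_modulus(2, 1, 1, 0.2),
               youngs_modulus(2, 1, 1, 0.1) / 2)
  expect_error(youngs_modulus(1, 0, 1, 0), "> 0")
})

test_that("bi-exponential fit is exact on noiseless model-class data", {
  tr <- generate_relaxation_trace(A = 2, B = 1, C = 5, tau1 = 60, tau2 = 5)
  f <- fit_double_exponential(tr$t, tr$tension_nN)
  expect_lt(abs(f$A - 2) / 2, 1e-6)
  expect_lt(abs(f$B - 1) / 1, 1e-6)
  expect_lt(abs(f$C - 5) / 5, 1e-6)
  expect_lt(abs(f$tau1 - 60) / 60, 1e-6)
  expect_lt(abs(f$tau2 - 5) / 5, 1e-6)
  expect_gte(f$tau1, f$tau2)
  expect_false(f$degenerate)
})

test_that("degenerate relaxations are flagged, not mis-fit", {
  # pure offset
  f0 <- fit_double_exponential(seq(0, 100, by = 1), rep(5, 101))
  expect_true(f0$degenerate)
  # single exponential (B = 0)
  tr <- generate_relaxation_trace(B = 0, tau2 = 5)
  f1 <- fit_double_exponential(tr$t, tr$tension_nN)
  expect_true(f1$degenerate)
  expect_lt(abs(f1$tau1 - 60) / 60, 1e-4)
  expect_error(fit_double_exponential(1:10, 1:10), "at least 20")
})

test_that("noisy recovery is near the information bound", {
  # Cramer-Rao for this design: sd(tau1)/tau1 ~ 8.8%, sd(tau2)/tau2 ~ 47%.
  # The estimator should be close to efficient, i.e. observed spread within
  # ~1.5x those bounds.
  set.seed(21)
  fits <- t(replicate(60, {
    y <- generate_relaxation_trace(noise_sd = 0.05)
    f <- fit_double_exponential(y$t, y$tension_nN)
    c(f$tau1, f$tau2)
  }))
  expect_lt(abs(stats::median(fits[, 1]) - 60) / 60, 0.05)
  expect_lt(abs(stats::median(fits[, 2]) - 5) / 5, 0.15)
  expect_lt(stats::mad(fits[, 1]) / 60, 1.5 * 0.088)
  expect_lt(stats::mad(fits[, 2]) / 5, 1.5 * 0.467)
})

test_that("softening curve on a model record falls with strain", {
  m <- axon_model(spectrin_species(n = 300))
  g <- default_geometry()
  # long waits: after a large step the decay is slower than the linearized
  # relaxation time, so give the plateau 10 of them
  rec <- generate_force_record(m, default_step_protocol(m, wait_factor = 10), g)
  gt <- attr(rec, "ground_truth")
  T0_true <- steady_state_tension_curve(0, m)$tension_nN
  soft <- softening_curve(record_to_trace(rec), g, T0 = T0_true)
  expect_equal(nrow(soft), 4)
  expect_equal(soft$Tss_nN, gt$Tss_nN, tolerance = 0.01)
  expect_true(all(diff(soft$E_kPa) < 0))
  expect_equal(attr(soft, "T0_nN"), T0_true)
  # extrapolated rest tension overestimates on a concave curve
  soft_ex <- softening_curve(record_to_trace(rec), g)
  expect_gt(attr(soft_ex, "T0_nN"), T0_true)
  expect_error(softening_curve(data.frame(), g), "empty|steps")
})

test_that("a linear elastic mock sample yields a constant modulus", {
  # cantilever-on-spring test: steady tension proportional to strain
  g <- default_geometry()
  gam <- rep(c(0.05, 0.1, 0.15, 0.2), each = 50)
  t <- seq_along(gam)
  stiff <- 5 # nN per unit strain
  tr <- structure(data.frame(t = t, gamma = gam, tension_nN = stiff * gam),
                  class = c("tension_trace", "data.frame"))
  soft <- softening_curve(tr, g, fit_relaxation = FALSE)
  # T0 extrapolates to 0 and E = stiff / A for every row
  expect_equal(attr(soft, "T0_nN"), 0, tolerance = 1e-10)
  expect_equal(soft$E_kPa, rep(stiff / g$A, 4), tolerance = 1e-8)
})

test_that("fitted slow relaxation times trace the analytic curve shape", {
  m <- axon_model(spectrin_species(n = 300))
  g <- default_geometry()
  pr <- default_step_protocol(m, gammas = seq(0.01, 0.20, by = 0.01))
  soft <- softening_curve(record_to_trace(generate_force_record(m, pr, g)), g)
  ta <- vapply(1 + soft$gamma, relaxation_time_analytic, numeric(1),
               species = spectrin_species())
  expect_gt(stats::cor(soft$tau1_s, ta, method = "spearman"), 0.8)
  # rise-then-fall: interior maximum
  expect_gt(which.max(soft$tau1_s), 1)
  expect_lt(which.max(soft$tau1_s), nrow(soft))
})
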