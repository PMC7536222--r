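test_that("the analytic relaxation has the right endpoints and midpoint value", {
  expect_equal(analytic_voltage(0, 130, 155, 10), 130)
  expect_equal(analytic_voltage(50 * 10, 130, 155, 10), 155,
               tolerance = 1e-9)
  # one time constant in: 155 - 25/e = 145.803 mV
  expect_equal(analytic_voltage(10, 130, 155, 10), 155 - 25 / exp(1),
               tolerance = 1e-12)
  expect_equal(analytic_voltage(10, 130, 155, 10), 145.803,
               tolerance = 1e-3)
  expect_error(analytic_voltage(1, 130, 155, -2), "tau")
})

test_that("forward simulation with an instant switch equals stitched closed-form segments", {
  cfg <- simulation_config()
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  an <- default_annotation(cfg)
  tm <- seq(0, 330, by = 2)
  got <- forward_simulate(p, an, ramp = 0, times = tm)
  want <- stitched_voltage(p, an, tm)
  expect_lt(max(abs(got$v - want)), 1e-9)
})

test_that("a trace started at the off-state steady state stays flat until mitotic entry", {
  cfg <- simulation_config()
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  an <- default_annotation(cfg)
  got <- forward_simulate(p, an, ramp = 4, times = seq(0, 330, by = 2))
  pre <- got$time <= an$t_g2m
  expect_equal(diff(range(got$v[pre])), 0, tolerance = 1e-9)
})

test_that("ramp integration is converged in step size and matches an adaptive dense integrator", {
  skip_if_not_installed("deSolve")
  cfg <- simulation_config()
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  an <- default_annotation(cfg)
  tm <- seq(0, 330, by = 2)
  coarse <- forward_simulate(p, an, ramp = 4, dt = 0.01, times = tm)
  fine <- forward_simulate(p, an, ramp = 4, dt = 0.0001, times = tm)
  expect_lt(max(abs(coarse$v - fine$v)), 1e-6)

  oracle <- lsoda_voltage(p, an, ramp = 4, times = tm)
  expect_lt(max(abs(coarse$v - oracle)), 1e-6)
})

test_that("segment fitting recovers noiseless exponentials to 0.1% across the tau range", {
  for (tau in c(2, 5, 12, 30, 100)) {
    span <- max(3.5 * tau, 40)
    tm <- seq(0, span, by = 2)
    v <- analytic_voltage(tm, 130, 160, tau)
    fit <- fit_segment(tm, v)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
    expect_lt(abs(fit$v_inf - 160), 0.1)
  }
})

test_that("flat segments are reported unidentifiable, not fitted", {
  tm <- seq(0, 40, by = 2)
  fit <- fit_segment(tm, rep(140, length(tm)))
  expect_false(fit$converged)
  expect_identical(fit$reason, "flat_segment")
  expect_error(fit_segment(tm[1:4], rep(1, 4)), ">= 5 points")
})

test_that("fitting is invariant to a global time shift", {
  tm <- seq(0, 40, by = 2)
  v <- analytic_voltage(tm, 130, 160, 12)
  f1 <- fit_segment(tm, v)
  f2 <- fit_segment(tm + 1234.5, v)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-9)
  expect_equal(f1$v_inf, f2$v_inf, tolerance = 1e-7)
})

test_that("tau recovery under 2% optical noise has bounded median error", {
  set.seed(123)
  s <- nernst_slope_mv()
  tm <- seq(0, 40, by = 2)
  truth <- analytic_voltage(tm, 130, 160, 12)
  errs <- replicate(500, {
    # multiplicative 2% CV on the dye signal = additive ~RT/F*0.02 on volts
    sdlog <- sqrt(log(1 + 0.02^2))
    noisy <- truth + s * rnorm(length(tm), 0, sdlog)
    fit <- fit_segment(tm, noisy)
    abs(fit$tau - 12) / 12
  })
  expect_lte(median(errs), 0.2)
})

test_that("noise-free cell fits recover the generating time constants within 1%", {
  cfg <- simulation_config(noise_cv = 0, intercell_cv = 0)
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  sim <- simulate_cell_trace(cfg, p, seed = 1)
  norm <- baseline_normalize(mass_normalize(sim$trace), sim$annotation)
  volt <- tmre_to_voltage(norm, v_baseline = cfg$v_baseline)
  fit <- fit_cell(volt, sim$annotation, ramp = cfg$transition_ramp)

  expect_lt(abs(fit$fit_on$tau - true_tau(p, "on")) / true_tau(p, "on"),
            0.01)
  expect_lt(abs(fit$fit_off$tau - true_tau(p, "off")) / true_tau(p, "off"),
            0.01)
  expect_gte(fit$v_peak, fit$v_g2)

  # bookkeeping: every sample between the windows is used, none in a ramp
  tm <- volt$time
  n_on_expected <- sum(tm >= sim$annotation$t_g2m + 4 &
                         tm <= sim$annotation$t_ma)
  expect_identical(fit$fit_on$n_points, as.integer(n_on_expected))
})

test_that("an oligomycin cell with matched non-ATP conductances relaxes more slowly", {
  cfg <- simulation_config(noise_cv = 0, intercell_cv = 0)
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  po <- oligomycin_params(p)
  fits <- lapply(list(control = p, oligo = po), function(pp) {
    cond <- if (pp$g_atp_on == 0) "oligomycin" else "control"
    sim <- simulate_cell_trace(cfg, pp, condition = cond, seed = 1)
    norm <- baseline_normalize(mass_normalize(sim$trace), sim$annotation)
    volt <- tmre_to_voltage(norm, v_baseline = cfg$v_baseline)
    fit_cell(volt, sim$annotation, ramp = cfg$transition_ramp)
  })
  expect_gt(fits$oligo$fit_on$tau, fits$control$fit_on$tau)
  expect_gt(fits$oligo$fit_off$tau, fits$control$fit_off$tau)
})

test_that("the non-ATP conductance partition verdicts follow the arithmetic", {
  seg <- function(tau) {
    structure(list(tau = tau, v0 = 130, v_inf = 150, rmse = 0,
                   n_points = 10, converged = TRUE, reason = NA_character_,
                   t0 = 0, span = 30),
              class = "segment_fit")
  }
  chk <- conductance_partition_check(seg(5), seg(10), 0.02, 0.06)
  expect_equal(chk$non_atp_on, 0.18)
  expect_equal(chk$non_atp_off, 0.04)
  expect_identical(chk$verdict, "increased")

  same <- conductance_partition_check(seg(8), seg(8), 0.03, 0.03)
  expect_identical(same$verdict, "unchanged")

  bad <- conductance_partition_check(seg(100), seg(10), 0.05, 0.06)
  expect_identical(bad$verdict, "inconsistent")
})

test_that("nearly all control cells show increased non-ATP conductance in mitosis", {
  co <- simulate_cohort(simulation_config(), n_control = 20, n_oligo = 20,
                        seed = 14)
  res <- analyze_cohort(co, n_boot = 50)
  verdicts <- vapply(res$fits[vapply(res$fits, function(f)
    f$condition == "control", logical(1))], function(f) {
      conductance_partition_check(f$fit_on, f$fit_off,
                                  res$kappa_on$kappa_atp,
                                  res$kappa_off$kappa_atp)$verdict
    }, character(1))
  expect_gte(mean(verdicts == "increased"), 0.95)
})

test_that("lower ATP-synthase conductance raises both the time constant and the steady state", {
  base <- circuit_params(325, 0.07, 0.04, 0.06, 0.01, 0.03, 0.05)
  lower <- circuit_params(325, 0.07, 0.04, 0.06, 0.01, 0.015, 0.05)
  for (st in c("on", "off")) {
    if (st == "off") next  # off-state g_atp identical in this pair
    s_base <- mitovolt:::epoch_steady_state(base, st)
    s_low <- mitovolt:::epoch_steady_state(lower, st)
    expect_gt(s_low$tau, s_base$tau)
    expect_gt(s_low$v_ss, s_base$v_ss)
  }
})
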