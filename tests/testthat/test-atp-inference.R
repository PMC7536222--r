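fake_fit <- function(tau_on, tau_off, v_g2 = 130, condition = "control",
                     cell_id = "c") {
  seg <- function(tau) {
    structure(list(tau = tau, v0 = 130, v_inf = 150, rmse = 0,
                   n_points = 10, converged = TRUE, reason = NA_character_,
                   t0 = 0, span = 30),
              class = "segment_fit")
  }
  structure(list(cell_id = cell_id, condition = condition,
                 fit_on = seg(tau_on), fit_off = seg(tau_off),
                 v_g2 = v_g2, v_peak = 150, exclusion_ramp = 4,
                 flags = character(0)),
            class = "circuit_fit")
}

test_that("conductance subtraction reproduces the two-cell arithmetic and degenerate cases", {
  ctrl <- list(fake_fit(10, 10), fake_fit(10, 10))
  oligo <- list(fake_fit(25, 25, condition = "oligomycin"),
                fake_fit(25, 25, condition = "oligomycin"))
  est <- estimate_g_atp(ctrl, oligo, state = "off")
  expect_equal(est$kappa_atp, 1 / 10 - 1 / 25, tolerance = 1e-12)
  expect_equal(est$kappa_atp, 0.06, tolerance = 1e-12)
  expect_equal(est$se, 0)

  same <- estimate_g_atp(ctrl, ctrl, state = "on")
  expect_equal(same$kappa_atp, 0)

  # oligomycin faster than control: clamped to zero with a warning
  expect_warning(neg <- estimate_g_atp(oligo, ctrl, state = "off"),
                 "clamped")
  expect_equal(neg$kappa_atp, 0)
  expect_lt(neg$kappa_atp_raw, 0)

  expect_error(estimate_g_atp(ctrl[1], oligo, state = "on"), ">= 2")
})

test_that("cohort-level ATP-synthase conductance recovery hits the generating truth", {
  cfg <- simulation_config(intercell_cv = 0.1)
  p <- control_circuit_params(cfg)
  co <- simulate_cohort(cfg, n_control = 40, n_oligo = 40, seed = 21,
                        params = p)
  res <- analyze_cohort(co, n_boot = 50)
  expect_lt(abs(res$kappa_off$kappa_atp - p$g_atp_off), 0.01)
  expect_lt(abs(res$kappa_on$kappa_atp - p$g_atp_on), 0.01)
})

test_that("relative ATP rate traces follow Ohm's law and the window averages", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  tm <- seq(0, 330, by = 2)

  # flat voltage, equal conductances: relative rate is identically 1
  flat <- voltage_trace("c1", tm, rep(130, length(tm)), 130, 26.73)
  prof <- atp_rate_trace(flat, an, kappa_on = 0.05, kappa_off = 0.05,
                         fit = fake_fit(7, 10), ramp = 4)
  expect_equal(unique(prof$i_atp_rel), 1)
  expect_equal(prof$early_mitosis_mean, 1, tolerance = 1e-12)
  expect_equal(total_atp_ratio(prof, "early_mitosis"), 1, tolerance = 1e-12)

  # constant mitotic voltage arithmetic: (150*0.02)/(130*0.06) = 0.3846
  tm1 <- seq(0, 330, by = 1)  # event times on the grid: window edges exact
  v <- ifelse(tm1 >= an$t_g2m & tm1 <= an$t_ma, 150, 130)
  vt <- voltage_trace("c1", tm1, v, 130, 26.73)
  prof2 <- atp_rate_trace(vt, an, kappa_on = 0.02, kappa_off = 0.06,
                          fit = fake_fit(7, 10), ramp = 0)
  expect_equal(prof2$early_mitosis_mean, (150 * 0.02) / (130 * 0.06),
               tolerance = 1e-6)
  expect_equal(1 - prof2$early_mitosis_mean, 0.615, tolerance = 1e-3)

  # time axis is aligned to the metaphase-anaphase transition
  expect_equal(prof2$time, tm1 - an$t_ma)
  expect_equal(prof2$windows$anaphase, c(0, 15))
})

test_that("fully blocked ATP synthase yields an identically zero profile", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  tm <- seq(0, 330, by = 2)
  vt <- voltage_trace("c1", tm, rep(260, length(tm)), 130, 26.73)
  prof <- atp_rate_trace(vt, an, kappa_on = 0, kappa_off = 0,
                         fit = fake_fit(7, 20, v_g2 = 260,
                                        condition = "oligomycin"))
  expect_true(all(prof$i_atp_rel == 0))
  expect_equal(total_atp_ratio(prof, "early_mitosis"), 0)
  expect_equal(total_atp_ratio(prof, "anaphase"), 0)
})

test_that("total ATP ratios equal the closed-form integral of the generating model", {
  # dense noise-free sampling, instant switch: trapezoid vs analytic integral
  cfg <- simulation_config(noise_cv = 0, intercell_cv = 0,
                           transition_ramp = 0)
  p <- control_circuit_params(simulation_config(), g_atp_on = 0.02)
  an <- default_annotation(cfg)
  tm <- seq(0, 330, by = 0.01)
  vt <- forward_simulate(p, an, ramp = 0, times = tm)
  vt$cell_id <- "dense"
  fit <- fake_fit(7, 10, v_g2 = 130)
  prof <- atp_rate_trace(vt, an, kappa_on = p$g_atp_on,
                         kappa_off = p$g_atp_off, fit = fit, ramp = 0)

  # closed form: integral of v_ss + (v0 - v_ss) e^(-t/tau) over the window
  on <- mitovolt:::epoch_steady_state(p, "on")
  dur <- an$t_ma - an$t_g2m
  int_v <- on$v_ss * dur + (130 - on$v_ss) * on$tau *
    (1 - exp(-dur / on$tau))
  want <- (int_v * p$g_atp_on) / (130 * p$g_atp_off * dur)
  expect_equal(total_atp_ratio(prof, "early_mitosis"), want,
               tolerance = 1e-6)
})

test_that("cohort aggregation reports mean with analytic and bootstrap SEM", {
  agg <- aggregate_cohort(c(1, 2, 3), n_boot = 200, seed = 3)
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem_analytic, 1 / sqrt(3), tolerance = 1e-12)

  flatv <- aggregate_cohort(rep(5, 10), n_boot = 100, seed = 3)
  expect_equal(flatv$sem_analytic, 0)
  expect_equal(flatv$sem_bootstrap, 0)

  expect_error(aggregate_cohort(1), ">= 2")

  # bootstrap SEM tracks the analytic SEM for Gaussian cohorts
  set.seed(8)
  ok <- replicate(60, {
    x <- rnorm(100)
    a <- aggregate_cohort(x, n_boot = 400, seed = sample.int(1e6, 1))
    abs(a$sem_bootstrap - a$sem_analytic) / a$sem_analytic < 0.15
  })
  expect_gte(mean(ok), 0.95)
})

test_that("bootstrap summaries are reproducible under a fixed seed", {
  x <- rnorm(50)
  a <- aggregate_cohort(x, n_boot = 300, seed = 12)
  b <- aggregate_cohort(x, n_boot = 300, seed = 12)
  expect_identical(a, b)
})
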