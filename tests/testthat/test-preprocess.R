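flat_signal <- function(value = 2, n = 166, dt = 2, cell_id = "c1") {
  tm <- seq(0, by = dt, length.out = n)
  structure(list(cell_id = cell_id, condition = "control", time = tm,
                 value = rep(value, n)),
            class = "cell_signal")
}

test_that("mass normalization divides fluorescence by mass elementwise", {
  tm <- seq(0, 100, by = 2)
  mass <- 50 * exp(0.04 * tm / 60)
  tr <- cell_trace("c1", "control", tm, mass, 2 * mass)
  expect_equal(mass_normalize(tr)$value, rep(2, length(tm)))

  tr2 <- cell_trace("c2", "control", tm, mass, rep(7, length(tm)))
  expect_true(all(diff(mass_normalize(tr2)$value) < 0))
})

test_that("mass-normalized noise-free signal equals the inverse Nernst image of the true voltage", {
  cfg <- simulation_config(noise_cv = 0, intercell_cv = 0)
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  sim <- simulate_cell_trace(cfg, p, seed = 1)
  sig <- mass_normalize(sim$trace)
  s <- nernst_slope_mv(cfg$temperature)
  expect_equal(sig$value, exp(sim$voltage_true / s), tolerance = 1e-12)
})

test_that("baseline normalization pins the window median at 1 and is idempotent", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  sig <- flat_signal(value = 7)
  norm <- baseline_normalize(sig, an)
  expect_equal(norm$value, rep(1, length(sig$time)))
  expect_length(norm$flags, 0)
  sel <- norm$time >= norm$baseline_window[["start"]] &
    norm$time <= norm$baseline_window[["end"]]
  expect_equal(median(norm$value[sel]), 1, tolerance = 1e-12)

  again <- baseline_normalize(norm, an)
  expect_equal(again$value, norm$value, tolerance = 1e-12)
})

test_that("short pre-abscission coverage is used as-is and flagged", {
  # trace starts 90 min before abscission
  tm <- seq(240, 330, by = 2)
  sig <- structure(list(cell_id = "c1", condition = "control", time = tm,
                        value = rep(3, length(tm))),
                   class = "cell_signal")
  an <- mitosis_annotation("c1", 255, 285, 330)
  norm <- baseline_normalize(sig, an, window = 180)
  expect_true("short_baseline" %in% norm$flags)
  expect_equal(norm$value, rep(1, length(tm)))
})

test_that("mitotic increase is the peak fractional rise over baseline", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  norm <- baseline_normalize(flat_signal(), an)
  expect_equal(mitotic_increase(norm, an), 0)

  bumped <- norm
  bumped$value[bumped$time == 284] <- 1.8
  expect_equal(mitotic_increase(bumped, an), 0.8)
})

test_that("synthetic noise-free mitotic increase matches the generating model", {
  cfg <- simulation_config(noise_cv = 0, intercell_cv = 0)
  p <- control_circuit_params(cfg, g_atp_on = 0.02)
  sim <- simulate_cell_trace(cfg, p, seed = 1)
  an <- sim$annotation
  norm <- baseline_normalize(mass_normalize(sim$trace), an)
  got <- mitotic_increase(norm, an)

  s <- nernst_slope_mv(cfg$temperature)
  raw <- exp(sim$voltage_true / s)
  sel_base <- sim$trace$time >= an$t_abscission - 180
  sel_mit <- sim$trace$time >= an$t_g2m
  want <- max(raw[sel_mit]) / median(raw[sel_base]) - 1
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("baseline QC passes flat traces, fails drifting ones, and is scale invariant", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  norm <- baseline_normalize(flat_signal(), an)
  qc <- qc_steady_baseline(norm, an)
  expect_true(qc$pass)
  expect_equal(qc$slope_per_hour, 0, tolerance = 1e-12)

  # +10%/h linear drift in the baseline window
  sig <- flat_signal()
  sig$value <- 1 + 0.10 * sig$time / 60
  drifting <- baseline_normalize(sig, an)
  qc2 <- qc_steady_baseline(drifting, an)
  expect_false(qc2$pass)
  expect_identical(qc2$reason, "unsteady_baseline")
  # raw +10%/h drift, rescaled by the window median (1 + 0.10 * 240/60)
  expect_equal(qc2$slope_per_hour, 0.10 / 1.4, tolerance = 1e-6)

  # multiplying the raw signal by a positive constant changes nothing
  scaled <- sig
  scaled$value <- sig$value * 37
  qc3 <- qc_steady_baseline(baseline_normalize(scaled, an), an)
  expect_equal(qc3$slope_per_hour, qc2$slope_per_hour, tolerance = 1e-12)

  short <- flat_signal(n = 4, dt = 2)
  an2 <- mitosis_annotation("c1", 1, 2, 6)
  norm4 <- structure(list(cell_id = "c1", time = short$time,
                          value = short$value,
                          baseline_window = c(start = 0, end = 6),
                          flags = character(0)),
                     class = "normalized_signal")
  expect_identical(qc_steady_baseline(norm4)$reason,
                   "insufficient_baseline")
})

test_that("QC passes >= 99% of flat-truth traces at the stated optical noise", {
  set.seed(99)
  an <- mitosis_annotation("c1", 255, 285, 330)
  tm <- seq(150, 330, by = 2)  # 91 baseline-window samples, 53 pre-mitotic
  n_pass <- 0
  n_rep <- 500
  sdlog <- sqrt(log(1 + 0.02^2))
  for (i in seq_len(n_rep)) {
    sig <- structure(list(cell_id = "c1", condition = "control", time = tm,
                          value = rlnorm(length(tm), -sdlog^2 / 2, sdlog)),
                     class = "cell_signal")
    qc <- qc_steady_baseline(baseline_normalize(sig, an), an)
    n_pass <- n_pass + qc$pass
  }
  expect_gte(n_pass / n_rep, 0.99)
})

test_that("Nernst conversion is exact at baseline, +18.53 mV per 2-fold signal, and invertible", {
  an <- mitosis_annotation("c1", 255, 285, 330)
  norm <- baseline_normalize(flat_signal(), an)
  v <- tmre_to_voltage(norm, v_baseline = 130, temperature = 310.15)
  expect_equal(v$v, rep(130, length(norm$time)), tolerance = 1e-12)
  expect_equal(v$nernst_slope, 26.73, tolerance = 0.005)

  doubled <- norm
  doubled$value <- rep(2, length(norm$value))
  v2 <- tmre_to_voltage(doubled, v_baseline = 130)
  expect_equal(v2$v[1] - 130, 18.53, tolerance = 0.005)

  # round trip to 1e-12 relative error
  wiggly <- norm
  set.seed(5)
  wiggly$value <- exp(rnorm(length(norm$value), 0, 0.3))
  back <- voltage_to_tmre(tmre_to_voltage(wiggly, v_baseline = 142))
  expect_equal(back$value, wiggly$value, tolerance = 1e-12)

  bad <- norm
  bad$value[3] <- -1
  expect_error(tmre_to_voltage(bad), "non-positive")
})
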