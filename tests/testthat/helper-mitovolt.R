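# Shared fixtures, built in code.

default_annotation <- function(config = simulation_config()) {
  mitosis_annotation("cell", config$t_g2m, config$t_ma, config$t_abscission)
}

# Stitched closed-form solution of the switched circuit for ramp = 0:
# independent of forward_simulate's integrator (oracle for the generator).
stitched_voltage <- function(params, annotation, times, v0 = NULL) {
  ss <- function(ge, gl, ga) {
    g <- ge + gl + ga
    c(v = params$emf * ge / g, tau = 1 / g)
  }
  off <- ss(params$g_etc_off, params$g_leak_off, params$g_atp_off)
  on <- ss(params$g_etc_on, params$g_leak_on, params$g_atp_on)
  if (is.null(v0)) v0 <- off[["v"]]
  v_at_g2m <- off[["v"]] + (v0 - off[["v"]]) *
    exp(-(annotation$t_g2m - times[1]) / off[["tau"]])
  v_at_ma <- on[["v"]] + (v_at_g2m - on[["v"]]) *
    exp(-(annotation$t_ma - annotation$t_g2m) / on[["tau"]])
  vapply(times, function(t) {
    if (t <= annotation$t_g2m) {
      off[["v"]] + (v0 - off[["v"]]) * exp(-(t - times[1]) / off[["tau"]])
    } else if (t <= annotation$t_ma) {
      on[["v"]] + (v_at_g2m - on[["v"]]) *
        exp(-(t - annotation$t_g2m) / on[["tau"]])
    } else {
      off[["v"]] + (v_at_ma - off[["v"]]) *
        exp(-(t - annotation$t_ma) / off[["tau"]])
    }
  }, numeric(1))
}

# Dense adaptive-ODE oracle (deSolve::lsoda), independent of the package's
# analytic-stitch + RK4 integrator.
lsoda_voltage <- function(params, annotation, ramp, times, v0 = NULL) {
  g_at <- function(t) {
    a <- if (t < annotation$t_g2m) 0
    else if (ramp > 0 && t < annotation$t_g2m + ramp)
      (t - annotation$t_g2m) / ramp
    else if (t < annotation$t_ma) 1
    else if (ramp > 0 && t < annotation$t_ma + ramp)
      1 - (t - annotation$t_ma) / ramp
    else 0
    list(ge = params$g_etc_off + a * (params$g_etc_on - params$g_etc_off),
         gl = params$g_leak_off + a * (params$g_leak_on - params$g_leak_off),
         ga = params$g_atp_off + a * (params$g_atp_on - params$g_atp_off))
  }
  if (is.null(v0)) {
    g0 <- params$g_etc_off + params$g_leak_off + params$g_atp_off
    v0 <- params$emf * params$g_etc_off / g0
  }
  rhs <- function(t, y, parms) {
    g <- g_at(t)
    list(g$ge * (params$emf - y) - (g$gl + g$ga) * y)
  }
  out <- deSolve::lsoda(c(v = v0), times, rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-11)
  unname(out[, "v"])
}

withr_like_tempdir <- function() {
  d <- tempfile("mitovolt-")
  dir.create(d)
  d
}

# A small deterministic cohort for I/O round-trip style tests.
tiny_cohort <- function(n = 3, seed = 11) {
  cfg <- simulation_config(noise_cv = 0.02, intercell_cv = 0.05)
  simulate_cohort(cfg, n_control = n, n_oligo = 1, seed = seed)
}

true_tau <- function(params, state) {
  1 / epoch_total_conductance(params, state)
}

epoch_total_conductance <- function(params, state) {
  if (state == "on") {
    params$g_etc_on + params$g_leak_on + params$g_atp_on
  } else {
    params$g_etc_off + params$g_leak_off + params$g_atp_off
  }
}
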