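#' Single-exponential RC relaxation
#'
#' Voltage across an RC circuit relaxing from `v0` toward the steady state
#' `v_inf` with time constant `tau`:
#' `v(t) = v_inf + (v0 - v_inf) * exp(-t / tau)`.
#'
#' @param t Time since the start of the relaxation (min); vectorized.
#' @param v0 Initial voltage (mV).
#' @param v_inf Asymptotic voltage (mV).
#' @param tau Time constant RC (min), must be positive.
#'
#' @return Voltage in mV, same length as `t`.
#' @export
analytic_voltage <- function(t, v0, v_inf, tau) {
  if (!is.finite(tau) || tau <= 0) stop("analytic_voltage: tau must be > 0")
  v_inf + (v0 - v_inf) * exp(-t / tau)
}

# Conductances (per unit capacitance, 1/min) at time t for a CDK1-switched
# circuit: OFF before t_g2m and after t_ma (+ramp), ON between, with linear
# interpolation over each transition ramp.
conductances_at <- function(t, params, annotation, ramp) {
  a <- if (t < annotation$t_g2m) {
    0
  } else if (ramp > 0 && t < annotation$t_g2m + ramp) {
    (t - annotation$t_g2m) / ramp
  } else if (t < annotation$t_ma) {
    1
  } else if (ramp > 0 && t < annotation$t_ma + ramp) {
    1 - (t - annotation$t_ma) / ramp
  } else {
    0
  }
  c(g_etc = params$g_etc_off + a * (params$g_etc_on - params$g_etc_off),
    g_leak = params$g_leak_off + a * (params$g_leak_on - params$g_leak_off),
    g_atp = params$g_atp_off + a * (params$g_atp_on - params$g_atp_off))
}

circuit_rhs <- function(t, v, params, annotation, ramp) {
  g <- conductances_at(t, params, annotation, ramp)
  g[["g_etc"]] * (params$emf - v) - (g[["g_leak"]] + g[["g_atp"]]) * v
}

# Steady state and time constant of a fixed-conductance epoch.
epoch_steady_state <- function(params, state = c("off", "on")) {
  state <- match.arg(state)
  g <- if (state == "on") {
    c(params$g_etc_on, params$g_leak_on, params$g_atp_on)
  } else {
    c(params$g_etc_off, params$g_leak_off, params$g_atp_off)
  }
  g_tot <- sum(g)
  list(v_ss = params$emf * g[1L] / g_tot, tau = 1 / g_tot, g_tot = g_tot)
}

# Classical RK4 from (t0, v0) to t1 with step <= dt; returns voltage at the
# (sorted, within [t0, t1]) output times plus the endpoint value.
rk4_segment <- function(t0, v0, t1, dt, params, annotation, ramp, t_out) {
  f <- function(t, v) circuit_rhs(t, v, params, annotation, ramp)
  grid <- sort(unique(c(seq(t0, t1, by = dt), t1, t_out)))
  v <- numeric(length(grid))
  v[1L] <- v0
  for (i in seq_len(length(grid) - 1L)) {
    h <- grid[i + 1L] - grid[i]
    if (h <= 0) { v[i + 1L] <- v[i]; next }
    k1 <- f(grid[i], v[i])
    k2 <- f(grid[i] + h / 2, v[i] + h / 2 * k1)
    k3 <- f(grid[i] + h / 2, v[i] + h / 2 * k2)
    k4 <- f(grid[i] + h, v[i] + h * k3)
    v[i + 1L] <- v[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(v_out = v[match(t_out, grid)], v_end = v[length(grid)])
}

#' Forward-simulate the CDK1-switched circuit voltage
#'
#' Solves the one-capacitor circuit
#' `dV/dt = g_etc (emf - V) - (g_leak + g_atp) V` with conductances switched
#' between the CDK1-off and CDK1-on parameter sets at `t_g2m` (off to on)
#' and `t_ma` (on to off). Within constant-parameter epochs the exact
#' single-exponential solution is used; across each transition ramp, where
#' conductances interpolate linearly between the two sets, the equation is
#' integrated numerically (RK4 with step `dt`).
#'
#' @param params Circuit parameters from [circuit_params].
#' @param annotation A [mitosis_annotation] defining the switch times.
#' @param ramp Transition ramp width in minutes (0 = instantaneous switch).
#' @param dt RK4 step inside ramp windows (min).
#' @param times Output times (min); defaults to a 2-min grid from 0 to
#'   `t_abscission`.
#' @param v0 Initial voltage at `times[1]`; defaults to the CDK1-off steady
#'   state (a cell in late G2).
#'
#' @return A `voltage_trace` (see [tmre_to_voltage]) with the simulated
#'   membrane-potential magnitude in mV.
#' @export
forward_simulate <- function(params, annotation, ramp = 4, dt = 0.01,
                             times = NULL, v0 = NULL) {
  stopifnot(inherits(annotation, "mitosis_annotation"))
  if (dt <= 0) stop("forward_simulate: dt must be > 0")
  if (ramp < 0) stop("forward_simulate: ramp must be >= 0")
  if (annotation$t_ma - annotation$t_g2m < ramp) {
    stop("forward_simulate: ramp longer than the CDK1-on epoch")
  }
  if (is.null(times)) times <- seq(0, annotation$t_abscission, by = 2)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("forward_simulate: times must increase")
  off <- epoch_steady_state(params, "off")
  on <- epoch_steady_state(params, "on")
  if (is.null(v0)) v0 <- off$v_ss

  t_start <- times[1L]
  # epoch boundaries, clipped to the requested span
  bounds <- c(annotation$t_g2m, annotation$t_g2m + ramp, annotation$t_ma,
              annotation$t_ma + ramp)
  knots <- sort(unique(c(t_start,
                         bounds[bounds > t_start & bounds < max(times)],
                         max(times))))

  v <- numeric(length(times))
  v_cur <- v0
  for (k in seq_len(length(knots) - 1L)) {
    a <- knots[k]; b <- knots[k + 1L]
    sel <- times > a & times <= b
    if (k == 1L) sel <- sel | times == a
    t_out <- times[sel]
    mid <- (a + b) / 2
    in_ramp <- ramp > 0 &&
      ((mid > annotation$t_g2m && mid < annotation$t_g2m + ramp) ||
       (mid > annotation$t_ma && mid < annotation$t_ma + ramp))
    if (in_ramp) {
      res <- rk4_segment(a, v_cur, b, dt, params, annotation, ramp, t_out)
      if (length(t_out)) v[sel] <- res$v_out
      v_cur <- res$v_end
    } else {
      ep <- if (mid > annotation$t_g2m && mid <= annotation$t_ma) on else off
      if (length(t_out)) {
        v[sel] <- analytic_voltage(t_out - a, v_cur, ep$v_ss, ep$tau)
      }
      v_cur <- analytic_voltage(b - a, v_cur, ep$v_ss, ep$tau)
    }
  }
  voltage_trace(cell_id = "simulated", time = times, v = v,
                v_baseline = off$v_ss, nernst_slope = NA_real_)
}

#' Fit a single-exponential relaxation to one voltage segment
#'
#' Bounded nonlinear least squares of [analytic_voltage] against a segment
#' of membrane-potential samples. The time constant is bounded in
#' `tau_bounds`; the fit is multi-started from tau = span/10, span/3 and
#' span (deterministic order) and the start with the lowest RMSE wins.
#' Flat segments, where the time constant is unidentifiable, are returned
#' unconverged with reason `"flat_segment"`.
#'
#' @param times Sample times (min), length >= 5.
#' @param volts Voltages (mV), same length.
#' @param tau_bounds Lower/upper bounds on tau (min).
#'
#' @return An object of class `segment_fit`: list with `tau`, `v0`, `v_inf`,
#'   `rmse`, `n_points`, `converged` and (when unconverged) `reason`.
#' @export
fit_segment <- function(times, volts, tau_bounds = c(0.1, 500)) {
  n <- length(times)
  if (n < 5L) stop("fit_segment: need >= 5 points, got ", n)
  stopifnot(length(volts) == n, all(is.finite(times)), all(is.finite(volts)))
  ord <- order(times)
  times <- times[ord]; volts <- volts[ord]
  tt <- times - times[1L]
  span <- tt[n]

  scale <- max(abs(volts), 1)
  if (diff(range(volts)) <= 1e-10 * scale) {
    return(structure(list(tau = NA_real_, v0 = volts[1L], v_inf = volts[n],
                          rmse = 0, n_points = n, converged = FALSE,
                          reason = "flat_segment", t0 = times[1L],
                          span = span),
                     class = "segment_fit"))
  }

  clamp <- function(x) min(max(x, tau_bounds[1L]), tau_bounds[2L])
  starts <- vapply(c(span / 10, span / 3, span), clamp, numeric(1))
  df <- data.frame(tt = tt, v = volts)
  best <- NULL
  for (tau0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ v_inf + (v0 - v_inf) * exp(-tt / tau),
        data = df,
        start = list(v0 = volts[1L], v_inf = volts[n], tau = tau0),
        lower = c(v0 = -1e6, v_inf = -1e6, tau = tau_bounds[1L]),
        upper = c(v0 = 1e6, v_inf = 1e6, tau = tau_bounds[2L]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse) {
      cf <- stats::coef(fit)
      best <- list(tau = unname(cf[["tau"]]), v0 = unname(cf[["v0"]]),
                   v_inf = unname(cf[["v_inf"]]), rmse = rmse)
    }
  }
  if (is.null(best)) {
    warning("fit_segment: optimizer failed to converge; returning ",
            "initialization values")
    return(structure(list(tau = clamp(span / 3), v0 = volts[1L],
                          v_inf = volts[n], rmse = NA_real_, n_points = n,
                          converged = FALSE, reason = "no_convergence",
                          t0 = times[1L], span = span),
                     class = "segment_fit"))
  }
  structure(c(best, list(n_points = n, converged = TRUE,
                         reason = NA_character_, t0 = times[1L],
                         span = span)),
            class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> tau = %.3f min, v0 = %.2f, v_inf = %.2f mV, rmse = %.3g (n = %d, %s)\n",
              x$tau, x$v0, x$v_inf, x$rmse, x$n_points,
              if (x$converged) "converged" else paste0("NOT converged: ", x$reason)))
  invisible(x)
}

#' Fit both CDK1 epochs of one cell
#'
#' Fits the CDK1-on relaxation over `[t_g2m + ramp, t_ma]` and the CDK1-off
#' recovery over `[t_ma + ramp, t_abscission]`; samples inside a transition
#' ramp contribute to neither fit. Also records the pre-mitotic reference
#' voltage `v_g2` (median over `[t_g2m - 60, t_g2m - 10]` min, clipped to
#' the available data) and `v_peak` (the sample nearest `t_ma`). Cells whose
#' on-state asymptote falls below `v_g2` are flagged
#' `"no_hyperpolarization"` but retained.
#'
#' @param voltage A `voltage_trace` (see [tmre_to_voltage]).
#' @param annotation A [mitosis_annotation].
#' @param ramp Transition-exclusion width (min), default 4.
#' @param condition Condition label carried into the result.
#' @param tau_bounds Bounds on the fitted time constant (min).
#'
#' @return An object of class `circuit_fit` with elements `fit_on`,
#'   `fit_off` (both [fit_segment] results), `v_g2`, `v_peak`, `flags`.
#' @export
fit_cell <- function(voltage, annotation, ramp = 4, condition = "control",
                     tau_bounds = c(0.1, 500)) {
  stopifnot(inherits(voltage, "voltage_trace"),
            inherits(annotation, "mitosis_annotation"))
  tm <- voltage$time
  v <- voltage$v

  sel_on <- tm >= annotation$t_g2m + ramp & tm <= annotation$t_ma
  sel_off <- tm >= annotation$t_ma + ramp & tm <= annotation$t_abscission
  if (sum(sel_on) < 5L) {
    stop("fit_cell '", voltage$cell_id, "': fewer than 5 usable samples in ",
         "the CDK1-on segment")
  }
  if (sum(sel_off) < 5L) {
    stop("fit_cell '", voltage$cell_id, "': fewer than 5 usable samples in ",
         "the CDK1-off segment")
  }
  fit_on <- fit_segment(tm[sel_on], v[sel_on], tau_bounds)
  fit_off <- fit_segment(tm[sel_off], v[sel_off], tau_bounds)

  sel_g2 <- tm >= annotation$t_g2m - 60 & tm <= annotation$t_g2m - 10
  if (!any(sel_g2)) sel_g2 <- tm < annotation$t_g2m
  if (!any(sel_g2)) {
    stop("fit_cell '", voltage$cell_id, "': no pre-mitotic samples for v_g2")
  }
  v_g2 <- stats::median(v[sel_g2])
  v_peak <- v[which.min(abs(tm - annotation$t_ma))]

  flags <- character(0)
  if (isTRUE(fit_on$converged) && fit_on$v_inf < v_g2) {
    flags <- c(flags, "no_hyperpolarization")
  }
  structure(
    list(cell_id = voltage$cell_id, condition = condition,
         fit_on = fit_on, fit_off = fit_off, v_g2 = v_g2, v_peak = v_peak,
         exclusion_ramp = ramp, flags = flags),
    class = "circuit_fit"
  )
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat(sprintf("<circuit_fit> %s [%s]: tau_on = %.2f, tau_off = %.2f min, v_g2 = %.1f, v_peak = %.1f mV%s\n",
              x$cell_id, x$condition, x$fit_on$tau, x$fit_off$tau, x$v_g2,
              x$v_peak,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Check the non-ATP conductance partition between CDK1 states
#'
#' For the ATP-synthase resistance to rise while the total time constant
#' falls during mitosis, the remaining (ETC + leak) conductance must rise.
#' Given the fitted per-state time constants and the cohort ATP-synthase
#' conductance estimates, computes the non-ATP conductance
#' `1/tau_state - g_atp_state` per state and reports whether it increased
#' in the CDK1-on state.
#'
#' @param fit_on,fit_off Converged [fit_segment] results for the two states.
#' @param g_atp_on,g_atp_off ATP-synthase conductance per capacitance
#'   (1/min) in each state.
#'
#' @return List with `non_atp_on`, `non_atp_off` (1/min) and `verdict`, one
#'   of `"increased"`, `"decreased"`, `"unchanged"`, or `"inconsistent"`
#'   (a negative implied non-ATP conductance, flagging a model violation).
#' @export
conductance_partition_check <- function(fit_on, fit_off, g_atp_on, g_atp_off) {
  if (!isTRUE(fit_on$converged) || !isTRUE(fit_off$converged)) {
    stop("conductance_partition_check: both fits must be converged")
  }
  stopifnot(g_atp_on >= 0, g_atp_off >= 0)
  non_on <- 1 / fit_on$tau - g_atp_on
  non_off <- 1 / fit_off$tau - g_atp_off
  verdict <- if (non_on < 0 || non_off < 0) {
    "inconsistent"
  } else if (abs(non_on - non_off) <= 1e-9 * max(non_on, non_off, 1e-12)) {
    "unchanged"
  } else if (non_on > non_off) {
    "increased"
  } else {
    "decreased"
  }
  list(non_atp_on = non_on, non_atp_off = non_off, verdict = verdict)
}
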