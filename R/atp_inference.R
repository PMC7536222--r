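sem_of <- function(x) stats::sd(x) / sqrt(length(x))

#' Extract the ATP-synthase conductance from a control vs oligomycin
#' comparison
#'
#' In the circuit model the fitted rate constant `1/tau` of a state equals
#' the total conductance `g_etc + g_leak + g_atp` of that state. Oligomycin
#' takes the ATP-synthase resistance to infinity (`g_atp = 0`), so under
#' the identifying assumption of equal capacitance and equal non-ATP
#' conductances across arms, the difference of typical rate constants
#' between control and oligomycin-treated cells is the ATP-synthase
#' conductance `kappa_atp = g_ATP / C` of that CDK1 state. Because `1/tau`
#' is a convex transform of a noisily fitted time constant, its per-cell
#' distribution is right-skewed and a plain arm mean is fragile to a few
#' poorly identified short-tau fits; the arm location is therefore taken
#' as the median by default (`aggregate = "mean"` restores the plain
#' difference of means). The standard error combines the two arm SEMs in
#' quadrature (for the median, 1.2533 x SEM, the asymptotic Gaussian
#' ratio); a negative raw estimate is clamped to zero with a warning (the
#' raw value is retained).
#'
#' @param control_fits,oligo_fits Lists of [fit_cell] results.
#' @param state `"on"` or `"off"` (CDK1 state).
#' @param aggregate `"median"` (default) or `"mean"`: arm location
#'   statistic for the per-cell rate constants.
#'
#' @return An object of class `conductance_estimate`: list with `state`,
#'   `kappa_atp` (1/min, clamped at 0), `kappa_atp_raw`, `se`,
#'   `n_control`, `n_oligo`.
#' @export
estimate_g_atp <- function(control_fits, oligo_fits,
                           state = c("on", "off"),
                           aggregate = c("median", "mean")) {
  state <- match.arg(state)
  aggregate <- match.arg(aggregate)
  pick <- function(fits) {
    slot <- if (state == "on") "fit_on" else "fit_off"
    taus <- vapply(fits, function(f) {
      sf <- f[[slot]]
      if (isTRUE(sf$converged)) sf$tau else NA_real_
    }, numeric(1))
    taus[is.finite(taus)]
  }
  tau_c <- pick(control_fits)
  tau_o <- pick(oligo_fits)
  if (length(tau_c) < 2L || length(tau_o) < 2L) {
    stop("estimate_g_atp: need >= 2 converged fits in each arm (control: ",
         length(tau_c), ", oligomycin: ", length(tau_o), ")")
  }
  rate_c <- 1 / tau_c
  rate_o <- 1 / tau_o
  if (aggregate == "median") {
    raw <- stats::median(rate_c) - stats::median(rate_o)
    se <- 1.2533 * sqrt(sem_of(rate_c)^2 + sem_of(rate_o)^2)
  } else {
    raw <- mean(rate_c) - mean(rate_o)
    se <- sqrt(sem_of(rate_c)^2 + sem_of(rate_o)^2)
  }
  kappa <- raw
  if (raw < 0) {
    warning("estimate_g_atp: negative raw conductance (", signif(raw, 3),
            " 1/min) clamped to 0")
    kappa <- 0
  }
  structure(
    list(state = state, kappa_atp = kappa, kappa_atp_raw = raw, se = se,
         n_control = length(tau_c), n_oligo = length(tau_o)),
    class = "conductance_estimate"
  )
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("<conductance_estimate> CDK1_%s: kappa_atp = %.4f +- %.4f 1/min (n = %d control, %d oligomycin)\n",
              x$state, x$kappa_atp, x$se, x$n_control, x$n_oligo))
  invisible(x)
}

# ATP-synthase conductance at time t: kappa_off outside mitosis, kappa_on
# inside, linearly interpolated across each transition ramp. With an
# instantaneous switch (ramp = 0) the on-state interval is closed at t_ma,
# so the window average over early mitosis uses the left limit at the peak.
kappa_at <- function(t, annotation, kappa_on, kappa_off, ramp) {
  a <- rep(0, length(t))
  a[t >= annotation$t_g2m & t <= annotation$t_ma] <- 1
  a[t > annotation$t_ma] <- 0
  if (ramp > 0) {
    up <- t >= annotation$t_g2m & t < annotation$t_g2m + ramp
    a[up] <- (t[up] - annotation$t_g2m) / ramp
    down <- t >= annotation$t_ma & t < annotation$t_ma + ramp
    a[down] <- 1 - (t[down] - annotation$t_ma) / ramp
  }
  kappa_off + a * (kappa_on - kappa_off)
}

# Trapezoidal time-average of y(t) over [a, b], with linear interpolation
# of the endpoints onto the window limits.
trapz_average <- function(time, y, a, b) {
  if (b <= a) stop("trapz_average: empty window")
  inside <- time > a & time < b
  ta <- stats::approx(time, y, xout = c(a, b), rule = 2)
  tg <- c(a, time[inside], b)
  yg <- c(ta$y[1L], y[inside], ta$y[2L])
  sum((yg[-1L] + yg[-length(yg)]) / 2 * diff(tg)) / (b - a)
}

#' Ohm's-law ATP synthesis rate profile for one cell
#'
#' The ATP synthesis current is `i_atp(t) = v(t) * kappa(t)` where
#' `kappa(t)` switches between the cohort-level CDK1-on and CDK1-off
#' ATP-synthase conductances (interpolated across the transition ramps).
#' Rates are reported relative to the cell's own G2 reference rate
#' `i_g2 = v_g2 * kappa_off`, and time is aligned so the
#' metaphase-anaphase transition sits at 0.
#'
#' @param voltage A `voltage_trace`.
#' @param annotation A [mitosis_annotation].
#' @param kappa_on,kappa_off ATP-synthase conductances (1/min) from
#'   [estimate_g_atp].
#' @param fit The cell's [fit_cell] result (supplies `v_g2`).
#' @param ramp Transition ramp width (min), default 4.
#'
#' @return An object of class `atp_profile`: list with `time` (min,
#'   `t_ma` = 0), `i_atp_rel`, `i_g2`, `early_mitosis_mean`,
#'   `anaphase_mean`, `total_ratio_early`, `total_ratio_anaphase`, and the
#'   window definitions.
#' @export
atp_rate_trace <- function(voltage, annotation, kappa_on, kappa_off, fit,
                           ramp = 4) {
  stopifnot(inherits(voltage, "voltage_trace"),
            inherits(annotation, "mitosis_annotation"))
  if (kappa_on < 0 || kappa_off < 0) {
    stop("atp_rate_trace: conductances must be >= 0")
  }
  i_g2 <- fit$v_g2 * kappa_off
  if (i_g2 == 0) {
    # fully blocked synthase (oligomycin): no reference rate, profile is 0
    if (kappa_on == 0 && kappa_off == 0) {
      i_rel <- rep(0, length(voltage$time))
      return(structure(
        list(cell_id = voltage$cell_id, time = voltage$time - annotation$t_ma,
             i_atp_rel = i_rel, i_g2 = 0, early_mitosis_mean = 0,
             anaphase_mean = 0, total_ratio_early = 0,
             total_ratio_anaphase = 0,
             windows = list(early = c(annotation$t_g2m, annotation$t_ma) -
                              annotation$t_ma,
                            anaphase = c(0, min(15, annotation$t_abscission -
                                                  annotation$t_ma)))),
        class = "atp_profile"))
    }
    stop("atp_rate_trace '", voltage$cell_id, "': zero G2 reference rate")
  }
  kap <- kappa_at(voltage$time, annotation, kappa_on, kappa_off, ramp)
  i_rel <- pmax(voltage$v * kap / i_g2, 0)
  t0 <- annotation$t_ma
  early <- c(annotation$t_g2m, annotation$t_ma)
  ana <- c(annotation$t_ma, min(annotation$t_ma + 15,
                                annotation$t_abscission))
  early_mean <- trapz_average(voltage$time, i_rel, early[1L], early[2L])
  ana_mean <- trapz_average(voltage$time, i_rel, ana[1L], ana[2L])
  structure(
    list(cell_id = voltage$cell_id, time = voltage$time - t0,
         i_atp_rel = i_rel, i_g2 = i_g2,
         early_mitosis_mean = early_mean, anaphase_mean = ana_mean,
         total_ratio_early = early_mean, total_ratio_anaphase = ana_mean,
         windows = list(early = early - t0, anaphase = ana - t0)),
    class = "atp_profile"
  )
}

#' Total ATP synthesized over a mitotic window, relative to G2 levels
#'
#' Trapezoidal integral of the ATP synthesis current over the window,
#' divided by what the null hypothesis (rate pinned at G2 level for the
#' same duration) would synthesize. Equals the time-average of the
#' relative rate.
#'
#' @param profile An `atp_profile` from [atp_rate_trace].
#' @param window `"early_mitosis"` (G2/M to M/A) or `"anaphase"` (15 min
#'   from M/A, clipped at abscission).
#'
#' @return The total-ATP ratio (unitless fraction).
#' @export
total_atp_ratio <- function(profile, window = c("early_mitosis", "anaphase")) {
  window <- match.arg(window)
  stopifnot(inherits(profile, "atp_profile"))
  w <- if (window == "early_mitosis") profile$windows$early else
    profile$windows$anaphase
  if (profile$i_g2 == 0) return(0)
  trapz_average(profile$time, profile$i_atp_rel, w[1L], w[2L])
}

#' Cohort mean with analytic and bootstrap SEM
#'
#' Summarizes per-cell fractions as mean +- SEM; the SEM is reported both
#' analytically (`sd/sqrt(n)`) and as the standard deviation of seeded
#' bootstrap-over-cells resampled means.
#'
#' @param values Numeric vector of per-cell values, length >= 2.
#' @param quantity Label describing the summarized quantity.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed for the bootstrap.
#'
#' @return An object of class `cohort_summary`: list with `quantity`,
#'   `mean`, `sem_analytic`, `sem_bootstrap`, `n_cells`, `n_boot`, `seed`.
#' @export
aggregate_cohort <- function(values, quantity = "value", n_boot = 1000,
                             seed = 7) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("aggregate_cohort: need >= 2 values")
  boot_means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  structure(
    list(quantity = quantity, mean = mean(values),
         sem_analytic = sem_of(values),
         sem_bootstrap = stats::sd(boot_means),
         n_cells = n, n_boot = n_boot, seed = seed),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: %.4f +- %.4f (analytic SEM; bootstrap %.4f, n = %d)\n",
              x$quantity, x$mean, x$sem_analytic, x$sem_bootstrap, x$n_cells))
  invisible(x)
}

#' Sensitivity of the early-mitosis estimate to model parameters
#'
#' Reruns the full analysis (Nernst conversion, epoch fitting, conductance
#' subtraction, profile averaging) over a grid of the assumed baseline
#' potential and the transition-ramp width, and tabulates the estimated
#' mean early-mitosis decrease at every grid point. Quantifies how little
#' the headline conclusion depends on the conversion constants.
#'
#' @param dataset A [cohort_dataset] with control and oligomycin cells.
#' @param grid List with numeric elements `v_baseline` (mV) and `ramp`
#'   (min); the full cross is evaluated.
#' @param ... Further analysis options passed to [analyze_cohort].
#'
#' @return A data frame with columns `v_baseline`, `ramp`,
#'   `mean_decrease`, `sem`, `n_cells`.
#' @export
sensitivity_scan <- function(dataset,
                             grid = list(v_baseline = c(100, 130, 180),
                                         ramp = c(0, 4, 8)),
                             ...) {
  pts <- expand.grid(v_baseline = grid$v_baseline, ramp = grid$ramp,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    res <- analyze_cohort(dataset, v_baseline = pts$v_baseline[i],
                          ramp = pts$ramp[i], ...)
    data.frame(v_baseline = pts$v_baseline[i], ramp = pts$ramp[i],
               mean_decrease = res$summary$decrease$mean,
               sem = res$summary$decrease$sem_analytic,
               n_cells = res$summary$decrease$n_cells)
  })
  do.call(rbind, rows)
}
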