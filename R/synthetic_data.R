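# Run code with a local, restored RNG state so simulation seeds never leak
# into (or depend on) the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation settings for synthetic single-cell trace cohorts
#'
#' Defaults emulate the measurement conditions of suspended-microchannel
#' single-cell dye monitoring: 2-min sampling, 2% CV multiplicative optical
#' noise, a ~30-min mitosis (G2/M at 255 min, metaphase-anaphase at
#' 285 min) followed by a 45-min cytokinesis ending in abscission, and
#' 10% log-normal inter-cell variability of circuit conductances.
#'
#' @param sampling_interval Sampling interval (min), default 2.
#' @param noise_cv Multiplicative log-normal fluorescence noise CV,
#'   default 0.02.
#' @param trace_duration Total trace length (min), default 330.
#' @param t_g2m,t_ma,t_abscission Event times (min); must satisfy
#'   `0 < t_g2m < t_ma < t_abscission <= trace_duration`.
#' @param transition_ramp Ramp (min) over which circuit conductances
#'   interpolate between CDK1 states, default 4 (two sampling intervals).
#' @param v_baseline Baseline (CDK1-off steady-state) membrane-potential
#'   magnitude (mV), default 130.
#' @param mass0 Initial buoyant mass (pg), default 50.
#' @param mass_growth_rate Exponential mass growth rate, fraction per hour,
#'   default 0.04.
#' @param intercell_cv Log-normal CV applied to per-cell circuit
#'   conductances, default 0.1.
#' @param temperature Assay temperature (K) for the dye partitioning,
#'   default 310.15.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_interval = 2, noise_cv = 0.02,
                              trace_duration = 330, t_g2m = 255, t_ma = 285,
                              t_abscission = 330, transition_ramp = 4,
                              v_baseline = 130, mass0 = 50,
                              mass_growth_rate = 0.04, intercell_cv = 0.1,
                              temperature = 310.15) {
  if (!(0 < t_g2m && t_g2m < t_ma && t_ma < t_abscission &&
        t_abscission <= trace_duration)) {
    stop("simulation_config: require 0 < t_g2m < t_ma < t_abscission <= ",
         "trace_duration")
  }
  if (sampling_interval <= 0) stop("simulation_config: sampling_interval must be > 0")
  if (noise_cv < 0) stop("simulation_config: noise_cv must be >= 0")
  if (intercell_cv < 0) stop("simulation_config: intercell_cv must be >= 0")
  if (transition_ramp < 0) stop("simulation_config: transition_ramp must be >= 0")
  structure(
    list(sampling_interval = sampling_interval, noise_cv = noise_cv,
         trace_duration = trace_duration, t_g2m = t_g2m, t_ma = t_ma,
         t_abscission = t_abscission, transition_ramp = transition_ramp,
         v_baseline = v_baseline, mass0 = mass0,
         mass_growth_rate = mass_growth_rate, intercell_cv = intercell_cv,
         temperature = temperature),
    class = "simulation_config"
  )
}

#' Ground-truth circuit parameters
#'
#' Conductances are expressed per unit membrane capacitance (1/min);
#' capacitance is fixed to 1 by convention, so only relative currents are
#' identifiable. `emf` is the effective electromotive force of the electron
#' transport chain "battery" (mV).
#'
#' @param emf Battery voltage (mV).
#' @param g_etc_on,g_etc_off ETC conductance per capacitance (1/min) in the
#'   CDK1-on / CDK1-off state.
#' @param g_leak_on,g_leak_off Proton-leak conductance (1/min).
#' @param g_atp_on,g_atp_off ATP-synthase conductance (1/min); both zero
#'   under oligomycin.
#'
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(emf, g_etc_on, g_etc_off, g_leak_on, g_leak_off,
                           g_atp_on, g_atp_off) {
  g <- c(g_etc_on = g_etc_on, g_etc_off = g_etc_off, g_leak_on = g_leak_on,
         g_leak_off = g_leak_off, g_atp_on = g_atp_on, g_atp_off = g_atp_off)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("circuit_params: conductances must be finite and >= 0")
  }
  if (!is.finite(emf) || emf <= 0) stop("circuit_params: emf must be > 0")
  structure(c(list(emf = emf, capacitance = 1), as.list(g)),
            class = "circuit_params")
}

# True time-averaged relative ATP current over a window, by dense RK4
# integration of the generating model (kappa interpolated across ramps,
# reference = v_baseline_true * g_atp_off).
true_relative_atp <- function(params, annotation, ramp,
                              window = c("early_mitosis", "anaphase"),
                              dt = 0.02) {
  window <- match.arg(window)
  lim <- if (window == "early_mitosis") {
    c(annotation$t_g2m, annotation$t_ma)
  } else {
    c(annotation$t_ma, min(annotation$t_ma + 15, annotation$t_abscission))
  }
  ts <- seq(lim[1L], lim[2L], by = dt)
  vt <- forward_simulate(params, annotation, ramp = ramp, dt = dt,
                         times = c(0, ts))
  v <- vt$v[-1L]
  kap <- vapply(ts, function(t) {
    conductances_at(t, params, annotation, ramp)[["g_atp"]]
  }, numeric(1))
  i_rel <- v * kap
  avg <- sum((i_rel[-1L] + i_rel[-length(i_rel)]) / 2 * diff(ts)) /
    diff(lim)
  v_base <- epoch_steady_state(params, "off")$v_ss
  avg / (v_base * params$g_atp_off)
}

#' Default control-cell circuit parameters
#'
#' Builds the cohort-level ground truth used by the synthetic generator.
#' The CDK1-off conductances give a 10-min off-state time constant; the
#' battery EMF is derived so the off-state steady state equals the
#' configured baseline potential. The CDK1-on ETC and leak conductances
#' rise (hyperpolarization), and the on-state ATP-synthase conductance is
#' calibrated by root-finding so that the generative time-averaged ATP
#' current over early mitosis is exactly `target_mitotic_fraction` of the
#' G2 rate (default 0.5, i.e. a 50% decrease).
#'
#' @param config A [simulation_config].
#' @param g_etc_off,g_leak_off,g_atp_off CDK1-off conductances (1/min).
#' @param g_etc_on,g_leak_on CDK1-on ETC and leak conductances (1/min).
#' @param g_atp_on CDK1-on ATP-synthase conductance; `NULL` (default) to
#'   calibrate against `target_mitotic_fraction`.
#' @param target_mitotic_fraction Designed early-mitosis ATP rate as a
#'   fraction of the G2 rate (default 0.5).
#'
#' @return A [circuit_params] object.
#' @export
control_circuit_params <- function(config = simulation_config(),
                                   g_etc_off = 0.04, g_leak_off = 0.01,
                                   g_atp_off = 0.05, g_etc_on = 0.07,
                                   g_leak_on = 0.06, g_atp_on = NULL,
                                   target_mitotic_fraction = 0.5) {
  g_tot_off <- g_etc_off + g_leak_off + g_atp_off
  emf <- config$v_baseline * g_tot_off / g_etc_off
  annotation <- mitosis_annotation("calibration", config$t_g2m, config$t_ma,
                                   config$t_abscission)
  if (is.null(g_atp_on)) {
    f <- function(g) {
      p <- circuit_params(emf, g_etc_on, g_etc_off, g_leak_on, g_leak_off,
                          g, g_atp_off)
      true_relative_atp(p, annotation, config$transition_ramp,
                        "early_mitosis") - target_mitotic_fraction
    }
    g_atp_on <- stats::uniroot(f, c(1e-5, 0.25), tol = 1e-10)$root
  }
  circuit_params(emf, g_etc_on, g_etc_off, g_leak_on, g_leak_off,
                 g_atp_on, g_atp_off)
}

#' Oligomycin counterpart of a parameter set
#'
#' Oligomycin blocks ATP synthase completely, taking its resistance to
#' infinity: both ATP-synthase conductances are set to zero, all other
#' parameters are kept.
#'
#' @param params A [circuit_params] object.
#' @return A [circuit_params] object with `g_atp_on = g_atp_off = 0`.
#' @export
oligomycin_params <- function(params) {
  circuit_params(params$emf, params$g_etc_on, params$g_etc_off,
                 params$g_leak_on, params$g_leak_off, 0, 0)
}

#' Simulate one single-cell trace
#'
#' Generates the forward circuit voltage for a cell spanning late G2
#' through abscission (starting at the CDK1-off steady state; no division
#' within the trace), maps it to fluorescence as
#' `mass(t) * exp(v(t) / (RT/F)) * noise` with multiplicative log-normal
#' noise of the configured CV (unit mean), and grows mass exponentially.
#'
#' @param config A [simulation_config].
#' @param params A [circuit_params] object.
#' @param condition Condition label (`"control"` or `"oligomycin"`); an
#'   oligomycin condition requires zero ATP-synthase conductances.
#' @param seed Integer seed for the noise draw (`NULL` = use current RNG).
#' @param cell_id Identifier for the generated cell.
#'
#' @return List with `trace` ([cell_trace]), `annotation`
#'   ([mitosis_annotation]), `params` (the ground truth used), and
#'   `voltage_true` (noise-free voltage at the sample times, mV).
#' @export
simulate_cell_trace <- function(config, params, condition = "control",
                                seed = NULL, cell_id = "cell_1") {
  stopifnot(inherits(config, "simulation_config"),
            inherits(params, "circuit_params"))
  if (condition == "oligomycin" &&
      (params$g_atp_on > 0 || params$g_atp_off > 0)) {
    stop("simulate_cell_trace: oligomycin condition requires zero ",
         "ATP-synthase conductances")
  }
  annotation <- mitosis_annotation(cell_id, config$t_g2m, config$t_ma,
                                   config$t_abscission)
  times <- seq(0, config$trace_duration, by = config$sampling_interval)
  vt <- forward_simulate(params, annotation, ramp = config$transition_ramp,
                         times = times)
  mass <- config$mass0 * exp(config$mass_growth_rate * times / 60)
  s <- nernst_slope_mv(config$temperature)
  noise <- with_seed(seed, {
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, length(times))
    }
  })
  fluor <- mass * exp(vt$v / s) * noise
  list(trace = cell_trace(cell_id, condition, times, mass, fluor),
       annotation = annotation, params = params, voltage_true = vt$v)
}

# One log-normal unit-mean jitter factor per conductance.
jitter_params <- function(params, cv) {
  if (cv <= 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  j <- function(x) {
    if (x == 0) 0 else x * stats::rlnorm(1, meanlog = -sdlog^2 / 2,
                                         sdlog = sdlog)
  }
  circuit_params(params$emf, j(params$g_etc_on), j(params$g_etc_off),
                 j(params$g_leak_on), j(params$g_leak_off),
                 j(params$g_atp_on), j(params$g_atp_off))
}

#' Simulate an annotated control + oligomycin cohort
#'
#' Draws per-cell circuit parameters log-normally around the cohort-level
#' truth (CV = `intercell_cv`), simulates every cell with the configured
#' optical noise, and returns a validated [cohort_dataset] with the
#' ground-truth parameters retained for recovery testing. Fixed seeds give
#' bit-reproducible cohorts.
#'
#' @param config A [simulation_config].
#' @param n_control,n_oligo Number of control / oligomycin cells.
#' @param seed Integer master seed.
#' @param params Cohort-level control parameters; defaults to
#'   [control_circuit_params] under `config`.
#'
#' @return A [cohort_dataset]; `true_params` holds each cell's
#'   [circuit_params].
#' @export
simulate_cohort <- function(config = simulation_config(), n_control = 40,
                            n_oligo = 40, seed = 1,
                            params = control_circuit_params(config)) {
  stopifnot(n_control >= 0, n_oligo >= 0)
  oligo_base <- oligomycin_params(params)
  with_seed(seed, {
    cells <- list()
    truths <- list()
    conds <- c(rep("control", n_control), rep("oligomycin", n_oligo))
    ids <- sprintf("%s_%03d", ifelse(conds == "control", "ctrl", "oligo"),
                   c(seq_len(n_control), seq_len(n_oligo)))
    for (i in seq_along(ids)) {
      base <- if (conds[i] == "control") params else oligo_base
      p_i <- jitter_params(base, config$intercell_cv)
      sim <- simulate_cell_trace(config, p_i, condition = conds[i],
                                 seed = NULL, cell_id = ids[i])
      cells[[ids[i]]] <- sim
      truths[[ids[i]]] <- p_i
    }
    cohort_dataset(
      traces = lapply(cells, `[[`, "trace"),
      annotations = lapply(cells, `[[`, "annotation"),
      provenance = sprintf(
        "simulate_cohort(n_control=%d, n_oligo=%d, seed=%s)",
        n_control, n_oligo, format(seed)),
      true_params = truths)
  })
}

#' Simulate synchrony-contaminated population flux samples
#'
#' Each synchronized population is a mixture of mitotic and G2 cells; its
#' measured flux is `f * x_mitosis + (1 - f) * x_g2` plus Gaussian
#' measurement noise.
#'
#' @param x_mitosis,x_g2 True per-state flux values (units carried through).
#' @param fractions Mitotic fractions in `[0, 1]`, one per sample.
#' @param noise_sd Gaussian measurement noise SD (flux units).
#' @param seed Integer seed (`NULL` = current RNG).
#'
#' @return A data frame with columns `sample_id`, `f_mitosis`, `f_g2`,
#'   `measured`.
#' @export
simulate_population_flux <- function(x_mitosis, x_g2, fractions,
                                     noise_sd = 0, seed = NULL) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("simulate_population_flux: fractions must lie in [0, 1]")
  }
  stopifnot(noise_sd >= 0)
  measured <- with_seed(seed, {
    fractions * x_mitosis + (1 - fractions) * x_g2 +
      stats::rnorm(length(fractions), 0, noise_sd)
  })
  data.frame(sample_id = sprintf("s%03d", seq_along(fractions)),
             f_mitosis = fractions, f_g2 = 1 - fractions,
             measured = measured, stringsAsFactors = FALSE)
}
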