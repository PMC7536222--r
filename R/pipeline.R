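default_config_blocks <- function() {
  list(
    simulate = list(n_control = 40, n_oligo = 40,
                    sampling_interval = 2, noise_cv = 0.02,
                    trace_duration = 330, t_g2m = 255, t_ma = 285,
                    t_abscission = 330, transition_ramp = 4,
                    v_baseline = 130, mass0 = 50, mass_growth_rate = 0.04,
                    intercell_cv = 0.1, temperature = 310.15,
                    target_mitotic_fraction = 0.5),
    paths = list(traces = NULL, annotations = NULL),
    preprocess = list(v_baseline = 130, window = 180,
                      slope_tolerance = 0.02, temperature = 310.15),
    fit = list(ramp = 4, tau_min = 0.1, tau_max = 500),
    infer = list(n_boot = 1000, boot_seed = 7,
                 ratio_convention = "mean_of_ratios"),
    seed = 1
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("pipeline_config: unknown key(s) in '", block, "': ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  defaults
}

#' Build a validated pipeline configuration
#'
#' Every parameter has a default; unknown keys are rejected. Blocks:
#' `simulate` (synthetic-cohort settings; ignored when `paths` point at
#' trace/annotation CSVs), `paths`, `preprocess` (conversion and QC),
#' `fit` (ramp and tau bounds), `infer` (bootstrap and ratio convention),
#' plus the top-level `seed`.
#'
#' @param simulate,paths,preprocess,fit,infer Named lists overriding
#'   defaults for the corresponding block.
#' @param seed Master seed for cohort simulation.
#'
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(simulate = list(), paths = list(),
                            preprocess = list(), fit = list(),
                            infer = list(), seed = 1) {
  d <- default_config_blocks()
  cfg <- list(
    simulate = merge_block(d$simulate, simulate, "simulate"),
    paths = merge_block(d$paths, paths, "paths"),
    preprocess = merge_block(d$preprocess, preprocess, "preprocess"),
    fit = merge_block(d$fit, fit, "fit"),
    infer = merge_block(d$infer, infer, "infer"),
    seed = seed
  )
  if (!cfg$infer$ratio_convention %in% c("mean_of_ratios", "ratio_of_means")) {
    stop("pipeline_config: ratio_convention must be 'mean_of_ratios' or ",
         "'ratio_of_means'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys mirror
#'   [pipeline_config] blocks.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_pipeline_config requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- c("simulate", "paths", "preprocess", "fit", "infer", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_pipeline_config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

qc_error <- function(qc_table) {
  structure(
    class = c("mitovolt_qc_error", "error", "condition"),
    list(message = "no_cells_after_qc: every cell failed baseline QC",
         call = NULL, qc_table = qc_table)
  )
}

#' Run the single-cell circuit analysis on an annotated cohort
#'
#' The analysis core shared by [run_pipeline] and [sensitivity_scan]:
#' mass- and baseline-normalizes every trace, applies steady-baseline QC,
#' converts the dye signal to approximate membrane potential, fits the
#' CDK1-on and CDK1-off relaxations of every QC-passed cell, extracts the
#' per-state ATP-synthase conductances from the control-vs-oligomycin
#' comparison, and derives per-cell relative ATP synthesis profiles for
#' the control cells.
#'
#' @param dataset A [cohort_dataset].
#' @param v_baseline Assumed baseline potential magnitude (mV).
#' @param window Baseline-normalization window (min).
#' @param slope_tolerance QC slope tolerance (fraction of baseline per
#'   hour).
#' @param temperature Assay temperature (K).
#' @param ramp Transition-exclusion ramp (min).
#' @param tau_bounds Bounds on fitted time constants (min).
#' @param n_boot,boot_seed Bootstrap settings for cohort summaries.
#' @param ratio_convention `"mean_of_ratios"` (average of per-cell relative
#'   rates; default) or `"ratio_of_means"`.
#'
#' @return List with `fits`, `profiles`, `voltages`, `kappa_on`,
#'   `kappa_off`, `qc_table`, and `summary` (cohort summaries of the
#'   early-mitosis decrease, anaphase change and total-ATP ratios).
#' @export
analyze_cohort <- function(dataset, v_baseline = 130, window = 180,
                           slope_tolerance = 0.02, temperature = 310.15,
                           ramp = 4, tau_bounds = c(0.1, 500),
                           n_boot = 1000, boot_seed = 7,
                           ratio_convention = "mean_of_ratios") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  ids <- names(dataset$traces)
  qc_rows <- list()
  voltages <- list()
  fits <- list()

  for (id in ids) {
    tr <- dataset$traces[[id]]
    an <- dataset$annotations[[id]]
    norm <- baseline_normalize(mass_normalize(tr), an, window = window)
    qc <- qc_steady_baseline(norm, an, slope_tolerance = slope_tolerance)
    qc_rows[[id]] <- data.frame(
      cell_id = id, condition = tr$condition, qc_pass = qc$pass,
      slope_per_hour = qc$slope_per_hour,
      reason = ifelse(is.na(qc$reason), "", qc$reason),
      stringsAsFactors = FALSE)
    if (!qc$pass) next
    # an assumed baseline far below the cell's true potential can push the
    # converted magnitude non-positive; treat that as a per-cell exclusion
    volt <- tryCatch(
      tmre_to_voltage(norm, v_baseline = v_baseline,
                      temperature = temperature),
      error = function(e) NULL)
    if (is.null(volt)) {
      qc_rows[[id]]$qc_pass <- FALSE
      qc_rows[[id]]$reason <- "voltage_conversion_failure"
      next
    }
    fit <- fit_cell(volt, an, ramp = ramp, condition = tr$condition,
                    tau_bounds = tau_bounds)
    voltages[[id]] <- volt
    fits[[id]] <- fit
  }
  qc_table <- do.call(rbind, qc_rows)
  rownames(qc_table) <- NULL
  if (length(fits) == 0L) stop(qc_error(qc_table))

  cond <- vapply(fits, function(f) f$condition, character(1))
  control_fits <- fits[cond == "control"]
  oligo_fits <- fits[cond == "oligomycin"]
  kappa_on <- estimate_g_atp(control_fits, oligo_fits, state = "on")
  kappa_off <- estimate_g_atp(control_fits, oligo_fits, state = "off")

  profiles <- lapply(names(control_fits), function(id) {
    atp_rate_trace(voltages[[id]], dataset$annotations[[id]],
                   kappa_on = kappa_on$kappa_atp,
                   kappa_off = kappa_off$kappa_atp,
                   fit = control_fits[[id]], ramp = ramp)
  })
  names(profiles) <- names(control_fits)

  early <- vapply(profiles, `[[`, numeric(1), "early_mitosis_mean")
  ana <- vapply(profiles, `[[`, numeric(1), "anaphase_mean")
  if (ratio_convention == "ratio_of_means") {
    i_g2 <- vapply(profiles, `[[`, numeric(1), "i_g2")
    dec_vals <- 1 - early * i_g2 / mean(i_g2)  # pooled-reference variant
  } else {
    dec_vals <- 1 - early
  }
  summary <- list(
    decrease = aggregate_cohort(dec_vals, "early_mitosis_decrease",
                                n_boot = n_boot, seed = boot_seed),
    anaphase_change = aggregate_cohort(ana - 1, "anaphase_change",
                                       n_boot = n_boot, seed = boot_seed),
    total_ratio_early = aggregate_cohort(early, "total_atp_ratio_early",
                                         n_boot = n_boot, seed = boot_seed),
    total_ratio_anaphase = aggregate_cohort(ana, "total_atp_ratio_anaphase",
                                            n_boot = n_boot, seed = boot_seed)
  )
  list(fits = fits, profiles = profiles, voltages = voltages,
       kappa_on = kappa_on, kappa_off = kappa_off, qc_table = qc_table,
       summary = summary)
}

fits_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, condition = f$condition,
               tau_on = f$fit_on$tau, tau_off = f$fit_off$tau,
               v_g2 = f$v_g2, v_peak = f$v_peak,
               rmse_on = f$fit_on$rmse, rmse_off = f$fit_off$rmse,
               converged_on = f$fit_on$converged,
               converged_off = f$fit_off$converged,
               flags = paste(f$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads, when `paths` are set) an annotated cohort, runs
#' [analyze_cohort], and assembles a reproducible report bundle: per-cell
#' fits and profiles, cohort summaries, the QC table, the echoed
#' configuration and all seeds. Deterministic given the configuration.
#'
#' @param config A [pipeline_config].
#'
#' @return An object of class `report_bundle`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$paths$traces)) {
    dataset <- read_cohort(config$paths$traces, config$paths$annotations)
  } else {
    s <- config$simulate
    sim_config <- simulation_config(
      sampling_interval = s$sampling_interval, noise_cv = s$noise_cv,
      trace_duration = s$trace_duration, t_g2m = s$t_g2m, t_ma = s$t_ma,
      t_abscission = s$t_abscission, transition_ramp = s$transition_ramp,
      v_baseline = s$v_baseline, mass0 = s$mass0,
      mass_growth_rate = s$mass_growth_rate, intercell_cv = s$intercell_cv,
      temperature = s$temperature)
    params <- control_circuit_params(
      sim_config, target_mitotic_fraction = s$target_mitotic_fraction)
    dataset <- simulate_cohort(sim_config, n_control = s$n_control,
                               n_oligo = s$n_oligo, seed = config$seed,
                               params = params)
  }
  res <- analyze_cohort(
    dataset, v_baseline = config$preprocess$v_baseline,
    window = config$preprocess$window,
    slope_tolerance = config$preprocess$slope_tolerance,
    temperature = config$preprocess$temperature,
    ramp = config$fit$ramp,
    tau_bounds = c(config$fit$tau_min, config$fit$tau_max),
    n_boot = config$infer$n_boot, boot_seed = config$infer$boot_seed,
    ratio_convention = config$infer$ratio_convention)

  structure(
    c(res, list(
      fits_table = fits_table(res$fits),
      config = unclass(config),
      software_version = as.character(utils::packageVersion("mitovolt")),
      seeds = list(cohort = config$seed, bootstrap = config$infer$boot_seed)
    )),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  d <- x$summary$decrease
  a <- x$summary$anaphase_change
  cat("<report_bundle>\n")
  cat(sprintf("  cells passing QC: %d of %d\n", nrow(x$fits_table),
              nrow(x$qc_table)))
  cat(sprintf("  kappa_atp (CDK1 on):  %.4f +- %.4f 1/min\n",
              x$kappa_on$kappa_atp, x$kappa_on$se))
  cat(sprintf("  kappa_atp (CDK1 off): %.4f +- %.4f 1/min\n",
              x$kappa_off$kappa_atp, x$kappa_off$se))
  cat(sprintf("  early-mitosis ATP synthesis decrease: %.1f%% +- %.1f%% (mean +- SEM, n = %d)\n",
              100 * d$mean, 100 * d$sem_analytic, d$n_cells))
  cat(sprintf("  anaphase ATP synthesis change: %+.1f%% +- %.1f%%\n",
              100 * a$mean, 100 * a$sem_analytic))
  cat(sprintf("  total ATP ratio, early mitosis: %.2f; anaphase: %.2f\n",
              x$summary$total_ratio_early$mean,
              x$summary$total_ratio_anaphase$mean))
  invisible(x)
}

summary_stats <- function(bundle) {
  list(
    n_cells_qc_pass = nrow(bundle$fits_table),
    n_cells_total = nrow(bundle$qc_table),
    kappa_atp_on = bundle$kappa_on$kappa_atp,
    kappa_atp_on_se = bundle$kappa_on$se,
    kappa_atp_off = bundle$kappa_off$kappa_atp,
    kappa_atp_off_se = bundle$kappa_off$se,
    early_mitosis_decrease = bundle$summary$decrease$mean,
    early_mitosis_decrease_sem = bundle$summary$decrease$sem_analytic,
    early_mitosis_decrease_sem_boot = bundle$summary$decrease$sem_bootstrap,
    anaphase_change = bundle$summary$anaphase_change$mean,
    anaphase_change_sem = bundle$summary$anaphase_change$sem_analytic,
    total_atp_ratio_early = bundle$summary$total_ratio_early$mean,
    total_atp_ratio_anaphase = bundle$summary$total_ratio_anaphase$mean,
    seeds = bundle$seeds,
    software_version = bundle$software_version
  )
}

#' Render a report bundle to files
#'
#' Writes a human-readable summary, the per-cell fit table (CSV), the
#' bundle statistics as JSON, and diagnostic figures: a voltage trace with
#' the fitted epoch relaxations overlaid, per-condition time-constant
#' boxplots, and a fan chart of per-cell relative ATP synthesis rates
#' aligned to the metaphase-anaphase transition (skipped when the bundle
#' carries no profiles).
#'
#' @param bundle A `report_bundle` from [run_pipeline].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, the character vector of written file paths.
#' @export
render_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("render_report: cannot create directory '", out_dir, "'")
  }
  paths <- character(0)

  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con); print(bundle); sink()
  close(con)
  paths <- c(paths, summary_path)

  fits_path <- file.path(out_dir, "fits.csv")
  utils::write.csv(bundle$fits_table, fits_path, row.names = FALSE)
  paths <- c(paths, fits_path)

  json_path <- file.path(out_dir, "bundle.json")
  jsonlite::write_json(summary_stats(bundle), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, json_path)

  # tau boxplots (per condition and CDK1 state)
  ft <- bundle$fits_table
  tau_df <- rbind(
    data.frame(condition = ft$condition, state = "CDK1_on", tau = ft$tau_on),
    data.frame(condition = ft$condition, state = "CDK1_off", tau = ft$tau_off))
  tau_df <- tau_df[is.finite(tau_df$tau), ]
  if (nrow(tau_df)) {
    p_tau <- ggplot2::ggplot(tau_df,
                             ggplot2::aes(x = condition, y = tau,
                                          fill = state)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "time constant RC (min)", x = NULL,
                    title = "Epoch time constants by condition") +
      ggplot2::theme_minimal()
    tau_path <- file.path(out_dir, "tau_boxplot.pdf")
    ggplot2::ggsave(tau_path, p_tau, width = 5, height = 4)
    paths <- c(paths, tau_path)
  }

  # fit overlay for the first control cell with a voltage trace
  ctrl_ids <- names(bundle$profiles)
  if (length(ctrl_ids)) {
    id <- ctrl_ids[[1L]]
    volt <- bundle$voltages[[id]]
    fit <- bundle$fits[[id]]
    df <- data.frame(time = volt$time, v = volt$v)
    p_fit <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = v)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::labs(x = "time (min)", y = "membrane potential (mV)",
                    title = paste0("Epoch fits: ", id)) +
      ggplot2::theme_minimal()
    for (slot in c("fit_on", "fit_off")) {
      sf <- fit[[slot]]
      if (isTRUE(sf$converged)) {
        seg <- data.frame(time = seq(sf$t0, sf$t0 + sf$span,
                                     length.out = 100))
        seg$v <- analytic_voltage(seg$time - sf$t0, sf$v0, sf$v_inf, sf$tau)
        p_fit <- p_fit +
          ggplot2::geom_line(data = seg,
                             mapping = ggplot2::aes(x = time, y = v),
                             inherit.aes = FALSE, colour = "red")
      }
    }
    fit_path <- file.path(out_dir, "fit_overlay.pdf")
    ggplot2::ggsave(fit_path, p_fit, width = 6, height = 4)
    paths <- c(paths, fit_path)
  }

  # fan chart of per-cell relative ATP synthesis rates, t_ma = 0
  if (length(bundle$profiles)) {
    fan <- do.call(rbind, lapply(bundle$profiles, function(p) {
      data.frame(cell_id = p$cell_id, time = p$time, i_rel = p$i_atp_rel)
    }))
    fan <- fan[fan$time >= -60 & fan$time <= 60, ]
    avg <- stats::aggregate(i_rel ~ time, data = fan, FUN = mean)
    p_fan <- ggplot2::ggplot(fan, ggplot2::aes(x = time, y = i_rel,
                                               group = cell_id)) +
      ggplot2::geom_line(alpha = 0.15) +
      ggplot2::geom_line(data = avg,
                         mapping = ggplot2::aes(x = time, y = i_rel),
                         inherit.aes = FALSE, linewidth = 1) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "time from metaphase-anaphase transition (min)",
                    y = "relative ATP synthesis rate (fraction of G2)",
                    title = "Per-cell ATP synthesis around division") +
      ggplot2::theme_minimal()
    fan_path <- file.path(out_dir, "atp_fan_chart.pdf")
    ggplot2::ggsave(fan_path, p_fan, width = 6, height = 4)
    paths <- c(paths, fan_path)
  }
  invisible(paths)
}
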