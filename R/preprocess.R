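# Physical constants (CODATA): gas constant J/(mol K), Faraday C/mol.
.GAS_CONSTANT <- 8.314462618
.FARADAY <- 96485.33212

#' Nernst slope RT/F in millivolts
#'
#' @param temperature Absolute temperature in kelvin (default 310.15 K,
#'   i.e. 37 degrees C).
#' @return RT/F in mV (~26.73 mV at 310.15 K).
#' @export
nernst_slope_mv <- function(temperature = 310.15) {
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}

#' Mass-normalize a fluorescence trace
#'
#' Divides fluorescence by buoyant mass sample-by-sample, removing the
#' trivial signal growth that tracks cell size. This is the quantity
#' plotted as "mass-normalized TMRE" in single-cell bioenergetic traces.
#'
#' @param trace A [cell_trace].
#' @return A `cell_signal`: list with `cell_id`, `condition`, `time` (min)
#'   and `value` (AU/pg).
#' @export
mass_normalize <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  structure(
    list(cell_id = trace$cell_id, condition = trace$condition,
         time = trace$time, value = trace$fluorescence / trace$buoyant_mass),
    class = "cell_signal"
  )
}

#' Baseline-normalize a signal to its pre-abscission median
#'
#' Divides every sample by the median signal over a window ending at
#' abscission (default 180 min, i.e. 3 h). If the trace covers less than
#' the full window, the available span is used and the result is flagged
#' `short_baseline`.
#'
#' @param signal A `cell_signal` from [mass_normalize] (or any list with
#'   `cell_id`, `time`, `value`).
#' @param annotation A [mitosis_annotation] supplying `t_abscission`.
#' @param window Baseline window length in minutes (default 180).
#'
#' @return A `normalized_signal`: list with `time`, `value` (baseline
#'   median = 1), `baseline_window` (start/end, min), and `flags`.
#' @export
baseline_normalize <- function(signal, annotation, window = 180) {
  stopifnot(inherits(annotation, "mitosis_annotation"), window > 0)
  t_end <- annotation$t_abscission
  t_start <- t_end - window
  flags <- character(0)
  if (min(signal$time) > t_start) {
    t_start <- min(signal$time)
    flags <- c(flags, "short_baseline")
  }
  sel <- signal$time >= t_start & signal$time <= t_end
  if (!any(sel)) stop("baseline_normalize '", signal$cell_id,
                      "': empty baseline window")
  med <- stats::median(signal$value[sel])
  if (!is.finite(med) || med <= 0) {
    stop("baseline_normalize '", signal$cell_id,
         "': non-positive baseline median")
  }
  structure(
    list(cell_id = signal$cell_id, condition = signal$condition,
         time = signal$time, value = signal$value / med,
         baseline_window = c(start = t_start, end = t_end), flags = flags),
    class = "normalized_signal"
  )
}

#' Peak mitotic signal increase
#'
#' The highest baseline-normalized signal between mitotic entry and
#' abscission, expressed as a fractional increase over baseline (a flat
#' trace gives 0; a 1.8-fold peak gives 0.8).
#'
#' @param norm A `normalized_signal`.
#' @param annotation A [mitosis_annotation].
#' @return Fractional increase (unitless).
#' @export
mitotic_increase <- function(norm, annotation) {
  stopifnot(inherits(norm, "normalized_signal"),
            inherits(annotation, "mitosis_annotation"))
  sel <- norm$time >= annotation$t_g2m & norm$time <= annotation$t_abscission
  if (!any(sel)) stop("mitotic_increase '", norm$cell_id,
                      "': no samples in the mitotic window")
  max(norm$value[sel]) - 1
}

#' QC: steady pre-mitotic baseline
#'
#' Cells whose dye signal has not reached a steady baseline before division
#' are excluded from circuit modeling. The verdict is based on the
#' least-squares slope of the normalized signal over the pre-mitotic part
#' of the baseline window (samples at or before `t_g2m` when an annotation
#' is given — the window itself extends through mitosis, where a slope
#' would only measure the mitotic spike), expressed as a fraction of
#' baseline per hour.
#'
#' @param norm A `normalized_signal`.
#' @param annotation Optional [mitosis_annotation]; when supplied, only
#'   baseline samples at or before `t_g2m` enter the slope fit.
#' @param slope_tolerance Pass threshold, fraction of baseline per hour
#'   (default 0.02, the optical noise floor).
#' @param min_baseline_span Minimum pre-mitotic baseline coverage in
#'   minutes (default 60); shorter coverage fails QC.
#'
#' @return List with `pass` (logical), `slope_per_hour` and `reason`
#'   (`NA` when passing, otherwise `"unsteady_baseline"`,
#'   `"insufficient_baseline"`, or `"short_baseline_span"`).
#' @export
qc_steady_baseline <- function(norm, annotation = NULL,
                               slope_tolerance = 0.02,
                               min_baseline_span = 60) {
  stopifnot(inherits(norm, "normalized_signal"))
  sel <- norm$time >= norm$baseline_window[["start"]] &
    norm$time <= norm$baseline_window[["end"]]
  if (!is.null(annotation)) {
    sel <- sel & norm$time <= annotation$t_g2m
  }
  tm <- norm$time[sel]
  if (length(tm) < 5L) {
    return(list(pass = FALSE, slope_per_hour = NA_real_,
                reason = "insufficient_baseline"))
  }
  if (diff(range(tm)) < min_baseline_span) {
    return(list(pass = FALSE, slope_per_hour = NA_real_,
                reason = "short_baseline_span"))
  }
  slope_min <- unname(stats::coef(stats::lm(norm$value[sel] ~ tm))[2L])
  slope_hr <- slope_min * 60
  pass <- abs(slope_hr) <= slope_tolerance
  list(pass = pass, slope_per_hour = slope_hr,
       reason = if (pass) NA_character_ else "unsteady_baseline")
}

#' Membrane-potential trace container
#'
#' @param cell_id Cell identifier.
#' @param time Sample times (min).
#' @param v Membrane-potential magnitudes (mV); positive, larger =
#'   hyperpolarized.
#' @param v_baseline Baseline potential magnitude (mV).
#' @param nernst_slope RT/F used for the conversion (mV), or `NA` for a
#'   simulated trace.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(cell_id, time, v, v_baseline, nernst_slope) {
  stopifnot(length(time) == length(v))
  if (any(v <= 0)) stop("voltage_trace '", cell_id,
                        "': potentials must be positive magnitudes")
  structure(
    list(cell_id = cell_id, time = as.numeric(time), v = as.numeric(v),
         v_baseline = v_baseline, nernst_slope = nernst_slope),
    class = "voltage_trace"
  )
}

#' Convert normalized dye signal to approximate membrane potential
#'
#' At non-quenching concentrations a cationic potentiometric dye (TMRE)
#' partitions into mitochondria Nernstianly, so the baseline-normalized
#' signal maps to a potential offset from the assumed baseline potential:
#' `v(t) = v_baseline + (RT/F) ln(signal(t))`. Potentials are stored as
#' positive magnitudes (hyperpolarization = increase).
#'
#' @param norm A `normalized_signal` with strictly positive values.
#' @param v_baseline Assumed baseline (G2) potential magnitude in mV
#'   (default 130).
#' @param temperature Assay temperature in kelvin (default 310.15).
#'
#' @return A [voltage_trace].
#' @export
tmre_to_voltage <- function(norm, v_baseline = 130, temperature = 310.15) {
  stopifnot(inherits(norm, "normalized_signal"))
  if (any(norm$value <= 0)) {
    stop("tmre_to_voltage '", norm$cell_id, "': non-positive signal values")
  }
  s <- nernst_slope_mv(temperature)
  voltage_trace(norm$cell_id, norm$time,
                v_baseline + s * log(norm$value),
                v_baseline = v_baseline, nernst_slope = s)
}

#' Inverse Nernst conversion: membrane potential back to normalized signal
#'
#' @param voltage A [voltage_trace] produced by [tmre_to_voltage].
#' @return A `normalized_signal` with `value = exp((v - v_baseline)/(RT/F))`.
#' @export
voltage_to_tmre <- function(voltage) {
  stopifnot(inherits(voltage, "voltage_trace"))
  if (!is.finite(voltage$nernst_slope)) {
    stop("voltage_to_tmre: voltage trace carries no Nernst slope")
  }
  structure(
    list(cell_id = voltage$cell_id, condition = NULL, time = voltage$time,
         value = exp((voltage$v - voltage$v_baseline) / voltage$nernst_slope),
         baseline_window = c(start = NA_real_, end = NA_real_),
         flags = character(0)),
    class = "normalized_signal"
  )
}
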