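#' Unmix a population flux into mitotic and G2 components
#'
#' Synchronized populations are imperfect mixtures of mitotic and G2 cells
#' (plus minor contamination from other phases). Given per-sample measured
#' fluxes and measured state fractions, solves the least-squares system
#' `measured_j = f_mitosis_j * x_M + f_g2_j * x_G2` for the per-state
#' fluxes, with fractions renormalized over `f_mitosis + f_g2`. The
#' solution is exact (zero residual) for two nondegenerate noiseless
#' samples. The simpler `method = "scale"` instead divides each sample by
#' its (renormalized) majority-state fraction and averages per state.
#'
#' @param samples Data frame with columns `measured`, `f_mitosis`, `f_g2`
#'   (as produced by [simulate_population_flux]).
#' @param method `"unmix"` (default, least squares) or `"scale"`.
#'
#' @return List with `x_mitosis`, `x_g2`, `residual` (root-mean-square
#'   residual; `NA` for `method = "scale"`), and `method`.
#' @export
unmix_two_state <- function(samples, method = c("unmix", "scale")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples),
            all(c("measured", "f_mitosis", "f_g2") %in% names(samples)))
  fm <- samples$f_mitosis
  fg <- samples$f_g2
  if (any(fm < 0 | fm > 1 | fg < 0 | fg > 1 | fm + fg > 1 + 1e-9)) {
    stop("unmix_two_state: fractions must lie in [0, 1] with ",
         "f_mitosis + f_g2 <= 1")
  }
  tot <- fm + fg
  if (any(tot <= 0)) stop("unmix_two_state: f_mitosis + f_g2 must be > 0")
  if (any(tot < 0.9)) {
    warning("unmix_two_state: sample(s) with f_mitosis + f_g2 < 0.9; ",
            "other-phase contamination is dropped by renormalization")
  }
  fm_n <- fm / tot
  fg_n <- fg / tot
  if (method == "scale") {
    mit <- fm_n >= 0.5
    if (!any(mit) || all(mit)) {
      stop("unmix_two_state(method='scale'): need samples of both ",
           "majority states")
    }
    return(list(x_mitosis = mean(samples$measured[mit] / fm_n[mit]),
                x_g2 = mean(samples$measured[!mit] / fg_n[!mit]),
                residual = NA_real_, method = method))
  }
  X <- cbind(f_mitosis = fm_n, f_g2 = fg_n)
  if (nrow(X) < 2L || qr(X)$rank < 2L) {
    stop("unmix_two_state: fraction matrix is rank deficient; need >= 2 ",
         "samples with distinct state fractions")
  }
  fit <- stats::lm.fit(X, samples$measured)
  list(x_mitosis = unname(fit$coefficients[["f_mitosis"]]),
       x_g2 = unname(fit$coefficients[["f_g2"]]),
       residual = sqrt(mean(fit$residuals^2)), method = method)
}

#' Decompose an oxygen-consumption series into respiratory components
#'
#' Standard mitochondrial stress-test algebra over a cell-count-normalized
#' OCR series with an oligomycin injection followed by rotenone +
#' antimycin A: basal respiration is the pre-oligomycin mean, the
#' oligomycin-sensitive drop is ATP-linked respiration (the mitochondrial
#' ATP synthesis rate), the remaining rotenone/antimycin-sensitive rate is
#' proton leak, and the residual is non-mitochondrial. By construction
#' `atp_linked + leak + non_mito = basal` exactly.
#'
#' @param times Measurement times (min).
#' @param ocr Oxygen-consumption rates (pmol O2/min), same length.
#' @param injections List with integer indices `oligomycin` and `rot_aa`:
#'   the first measurement taken after each injection.
#' @param drop_first_post_injection Drop the first measurement after each
#'   injection (mixing artifact)? Default `TRUE`.
#'
#' @return List with `basal`, `atp_linked`, `leak`, `non_mito` (same units
#'   as `ocr`) and `flags` (contains `"negative_component"` when
#'   post-oligomycin respiration exceeds basal or leak comes out negative).
#' @export
ocr_decompose <- function(times, ocr, injections,
                          drop_first_post_injection = TRUE) {
  n <- length(ocr)
  stopifnot(length(times) == n, all(diff(times) > 0))
  i1 <- injections$oligomycin
  i2 <- injections$rot_aa
  if (is.null(i1) || is.null(i2) || i1 >= i2 || i1 < 2L || i2 > n) {
    stop("ocr_decompose: injections must satisfy 1 < oligomycin < rot_aa <= ",
         "number of measurements")
  }
  basal_idx <- seq_len(i1 - 1L)
  oligo_idx <- seq.int(i1, i2 - 1L)
  rot_idx <- seq.int(i2, n)
  if (drop_first_post_injection) {
    if (length(oligo_idx) > 1L) oligo_idx <- oligo_idx[-1L]
    if (length(rot_idx) > 1L) rot_idx <- rot_idx[-1L]
  }
  if (length(basal_idx) < 2L || length(oligo_idx) < 2L ||
      length(rot_idx) < 2L) {
    stop("ocr_decompose: fewer than 2 usable measurements in a phase")
  }
  basal <- mean(ocr[basal_idx])
  post_oligo <- mean(ocr[oligo_idx])
  non_mito <- mean(ocr[rot_idx])
  atp_linked <- basal - post_oligo
  leak <- post_oligo - non_mito
  flags <- character(0)
  if (atp_linked < 0 || leak < 0) flags <- c(flags, "negative_component")
  list(basal = basal, atp_linked = atp_linked, leak = leak,
       non_mito = non_mito, flags = flags)
}

#' Lactate efflux rate by linear fit
#'
#' Ordinary least-squares slope of medium lactate concentration against
#' collection time (the glycolytic efflux rate), with its standard error.
#'
#' @param timepoints Collection times (min), strictly increasing after
#'   sorting; length >= 2.
#' @param concentrations Lactate amounts (e.g. nmol per 1e6 cells), same
#'   length.
#'
#' @return List with `slope` (concentration units per min), `se` (`NA`
#'   with flag `"no_residual_df"` when only 2 points), `residual_rms`,
#'   `n`, `flags`.
#' @export
lactate_efflux_rate <- function(timepoints, concentrations) {
  n <- length(timepoints)
  if (n < 2L) stop("lactate_efflux_rate: need >= 2 timepoints")
  stopifnot(length(concentrations) == n)
  ord <- order(timepoints)
  timepoints <- timepoints[ord]
  concentrations <- concentrations[ord]
  if (any(diff(timepoints) <= 0)) {
    stop("lactate_efflux_rate: timepoints must be distinct")
  }
  fit <- stats::lm(concentrations ~ timepoints)
  slope <- unname(stats::coef(fit)[2L])
  flags <- character(0)
  if (n == 2L) {
    se <- NA_real_
    flags <- c(flags, "no_residual_df")
  } else {
    # collinear inputs give a zero-residual fit; the SE (0) is still valid
    se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  }
  list(slope = slope, se = se,
       residual_rms = sqrt(mean(stats::residuals(fit)^2)), n = n,
       flags = flags)
}
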