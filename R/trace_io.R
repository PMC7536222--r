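#' Single-cell trace container
#'
#' A `cell_trace` holds one cell's sampled record: time (minutes), buoyant
#' mass (pg) and raw fluorescence (arbitrary units), together with the
#' experimental condition and fluorescence channel.
#'
#' @param cell_id Character scalar, unique within a cohort.
#' @param condition Condition label, typically `"control"` or `"oligomycin"`.
#' @param time Numeric vector of sampling times in minutes, strictly
#'   increasing.
#' @param buoyant_mass Numeric vector of buoyant masses in pg, all positive.
#' @param fluorescence Numeric vector of fluorescence values (AU).
#' @param channel Dye channel label, default `"TMRE"`.
#'
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, condition, time, buoyant_mass, fluorescence,
                       channel = "TMRE") {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  n <- length(time)
  if (n < 10L) {
    stop("cell_trace '", cell_id, "': need at least 10 samples, got ", n)
  }
  if (length(buoyant_mass) != n || length(fluorescence) != n) {
    stop("cell_trace '", cell_id, "': time, buoyant_mass and fluorescence ",
         "must have equal length")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop("cell_trace '", cell_id, "': time must be strictly increasing ",
         "(violation at sample ", bad, ")")
  }
  if (any(!is.finite(buoyant_mass)) || any(buoyant_mass <= 0)) {
    stop("cell_trace '", cell_id, "': buoyant_mass must be positive")
  }
  if (any(!is.finite(fluorescence))) {
    stop("cell_trace '", cell_id, "': fluorescence must be finite")
  }
  structure(
    list(cell_id = cell_id, condition = as.character(condition),
         channel = as.character(channel), time = as.numeric(time),
         buoyant_mass = as.numeric(buoyant_mass),
         fluorescence = as.numeric(fluorescence)),
    class = "cell_trace"
  )
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %s [%s, %s]: %d samples, %.1f-%.1f min\n",
              x$cell_id, x$condition, x$channel, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Cell-cycle event annotation
#'
#' The three events that delimit the CDK1 epochs of one cell: mitotic entry
#' (G2/M transition), metaphase-anaphase transition, and abscission of the
#' daughter cells. CDK1 is active on `(t_g2m, t_ma)` and inactive elsewhere.
#'
#' @param cell_id Character scalar matching a trace.
#' @param t_g2m,t_ma,t_abscission Event times in minutes with
#'   `t_g2m < t_ma < t_abscission`.
#'
#' @return An object of class `mitosis_annotation`.
#' @export
mitosis_annotation <- function(cell_id, t_g2m, t_ma, t_abscission) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  if (!(is.finite(t_g2m) && is.finite(t_ma) && is.finite(t_abscission))) {
    stop("mitosis_annotation '", cell_id, "': event times must be finite")
  }
  if (!(t_g2m < t_ma && t_ma < t_abscission)) {
    stop("mitosis_annotation '", cell_id, "': require t_g2m < t_ma < ",
         "t_abscission, got (", t_g2m, ", ", t_ma, ", ", t_abscission, ")")
  }
  structure(
    list(cell_id = cell_id, t_g2m = as.numeric(t_g2m), t_ma = as.numeric(t_ma),
         t_abscission = as.numeric(t_abscission)),
    class = "mitosis_annotation"
  )
}

#' Cohort of annotated single-cell traces
#'
#' Bundles traces with their per-cell event annotations. Every trace must
#' have exactly one annotation whose events fall inside the trace's time
#' span; optional ground-truth circuit parameters (for simulated cohorts)
#' ride along for recovery testing.
#'
#' @param traces List of [cell_trace] objects.
#' @param annotations List of [mitosis_annotation] objects.
#' @param provenance Free-text provenance string (generator settings, seed).
#' @param true_params Optional named list of per-cell true circuit parameters
#'   (simulated cohorts only).
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(traces, annotations, provenance = "",
                           true_params = NULL) {
  stopifnot(is.list(traces), is.list(annotations))
  ids <- vapply(traces, function(x) x$cell_id, character(1))
  if (anyDuplicated(ids)) {
    stop("cohort_dataset: duplicated cell_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  aids <- vapply(annotations, function(x) x$cell_id, character(1))
  if (!setequal(ids, aids) || length(aids) != length(ids)) {
    orphan <- union(setdiff(ids, aids), setdiff(aids, ids))
    stop("cohort_dataset: traces and annotations must match 1:1; ",
         "unmatched cell_id: ", paste(orphan, collapse = ", "))
  }
  names(traces) <- ids
  names(annotations) <- aids
  annotations <- annotations[ids]
  for (id in ids) {
    tr <- traces[[id]]
    an <- annotations[[id]]
    if (an$t_g2m < min(tr$time) || an$t_abscission > max(tr$time)) {
      stop("cohort_dataset: annotation events for cell '", id,
           "' fall outside the trace time span [", min(tr$time), ", ",
           max(tr$time), "]")
    }
  }
  structure(
    list(traces = traces, annotations = annotations,
         provenance = provenance, true_params = true_params),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cond <- table(vapply(x$traces, function(t) t$condition, character(1)))
  cat(sprintf("<cohort_dataset> %d cells (%s)\n", length(x$traces),
              paste(sprintf("%s: %d", names(cond), cond), collapse = ", ")))
  invisible(x)
}

# full-precision numeric formatting so that read(write(x)) == x exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort to delimited text files
#'
#' Writes two CSV files with deterministic column order and full-precision
#' ("%.17g") numeric formatting: `traces.csv` with columns
#' `cell_id,condition,channel,time_min,mass_pg,fluor_au` (one row per
#' sample) and `annotations.csv` with columns
#' `cell_id,t_g2m_min,t_ma_min,t_abscission_min`. Two writes of the same
#' dataset produce byte-identical files; [read_cohort] reproduces the
#' dataset exactly.
#'
#' @param dataset A [cohort_dataset].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, a named character vector with elements `traces` and
#'   `annotations` giving the written file paths.
#' @export
write_cohort <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_cohort: cannot create directory '", out_dir, "'")
  }
  trace_path <- file.path(out_dir, "traces.csv")
  annot_path <- file.path(out_dir, "annotations.csv")

  trace_lines <- "cell_id,condition,channel,time_min,mass_pg,fluor_au"
  for (tr in dataset$traces) {
    trace_lines <- c(trace_lines, paste(
      tr$cell_id, tr$condition, tr$channel,
      fmt_num(tr$time), fmt_num(tr$buoyant_mass), fmt_num(tr$fluorescence),
      sep = ","))
  }
  annot_lines <- "cell_id,t_g2m_min,t_ma_min,t_abscission_min"
  for (an in dataset$annotations) {
    annot_lines <- c(annot_lines, paste(
      an$cell_id, fmt_num(an$t_g2m), fmt_num(an$t_ma),
      fmt_num(an$t_abscission), sep = ","))
  }
  writeLines(trace_lines, trace_path)
  writeLines(annot_lines, annot_path)
  invisible(c(traces = trace_path, annotations = annot_path))
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "': missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

num_col <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop("'", path, "': column '", col, "' has a missing or non-numeric ",
         "value at line ", bad[1L] + 1L)  # +1 for header
  }
  x
}

#' Read a cohort from delimited text files
#'
#' Reads the trace/annotation CSV dialect written by [write_cohort] and
#' returns a fully validated [cohort_dataset]. Validation failures name the
#' offending cell and, where applicable, the file line.
#'
#' @param trace_path Path to the long-format trace CSV.
#' @param annotation_path Path to the annotation CSV.
#'
#' @return A [cohort_dataset].
#' @export
read_cohort <- function(trace_path, annotation_path) {
  tdf <- read_csv_strict(trace_path, c("cell_id", "condition", "channel",
                                       "time_min", "mass_pg", "fluor_au"))
  if (nrow(tdf) == 0L) stop("'", trace_path, "': no records")
  tdf$time_min <- num_col(tdf, "time_min", trace_path)
  tdf$mass_pg <- num_col(tdf, "mass_pg", trace_path)
  tdf$fluor_au <- num_col(tdf, "fluor_au", trace_path)

  adf <- read_csv_strict(annotation_path,
                         c("cell_id", "t_g2m_min", "t_ma_min",
                           "t_abscission_min"))
  if (nrow(adf) == 0L) stop("'", annotation_path, "': no records")
  for (col in c("t_g2m_min", "t_ma_min", "t_abscission_min")) {
    adf[[col]] <- num_col(adf, col, annotation_path)
  }

  traces <- lapply(split(seq_len(nrow(tdf)), tdf$cell_id)[unique(tdf$cell_id)],
                   function(idx) {
    sub <- tdf[idx, ]
    cond <- unique(sub$condition)
    chan <- unique(sub$channel)
    if (length(cond) != 1L || length(chan) != 1L) {
      stop("'", trace_path, "': cell '", sub$cell_id[1L],
           "' has inconsistent condition/channel labels")
    }
    cell_trace(sub$cell_id[1L], cond, sub$time_min, sub$mass_pg,
               sub$fluor_au, channel = chan)
  })
  annotations <- lapply(seq_len(nrow(adf)), function(i) {
    mitosis_annotation(adf$cell_id[i], adf$t_g2m_min[i], adf$t_ma_min[i],
                       adf$t_abscission_min[i])
  })
  cohort_dataset(traces, annotations,
                 provenance = paste0("read_cohort('", trace_path, "')"))
}
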