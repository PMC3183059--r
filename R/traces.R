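## Level traces and plate runs.  A level trace is the raw instrument record
## for one well: O2 tension (mmHg) and pH sampled through repeated
## mix/wait/measure cycles.  A plate run bundles the 24 traces with the
## layout and injection schedule.

## cycle template, minutes: sensor up and stirring (mix), settling (wait),
## sensor down forming the transient microchamber (measure)
CYCLE_TEMPLATE <- c(mix = 2, wait = 1, measure = 1.5)
CYCLE_MINUTES <- sum(CYCLE_TEMPLATE)
PHASES <- names(CYCLE_TEMPLATE)

TRACE_COLUMNS <- c("well", "time_min", "cycle", "phase", "O2_mmHg", "pH")

#' Construct a plate run
#'
#' @param traces long-format data frame with columns `well`, `time_min`,
#'   `cycle`, `phase`, `O2_mmHg`, `pH`.
#' @param layout a [plate_layout()].
#' @param schedule an [injection_schedule()], or `NULL` for a basal-only run.
#' @param n_cycles total measurement cycles; inferred from the traces when
#'   omitted.
#' @return A `plate_run` object.
#' @export
plate_run <- function(traces, layout, schedule = NULL, n_cycles = NULL) {
  check_traces(traces)
  traces$well <- normalize_well(traces$well)
  unknown <- setdiff(unique(traces$well), normalize_well(layout$well))
  if (length(unknown) > 0)
    abort(paste0("trace well(s) not in layout: ",
                 paste(unknown, collapse = ", ")),
          "fluxdeconv_layout_error")
  traces <- traces[order(traces$well, traces$time_min), , drop = FALSE]
  rownames(traces) <- NULL
  run <- list(
    traces = traces,
    layout = layout,
    schedule = schedule,
    n_cycles = n_cycles %||% max(traces$cycle)
  )
  class(run) <- "plate_run"
  run
}

check_traces <- function(traces) {
  miss <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(miss) > 0)
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          "fluxdeconv_format_error")
  bad_well <- unique(traces$well[!is_valid_well(traces$well)])
  if (length(bad_well) > 0)
    abort(paste0("unknown well ID(s): ",
                 paste(unique(bad_well), collapse = ", ")),
          "fluxdeconv_layout_error")
  if (any(!traces$phase %in% PHASES))
    abort(paste0("unknown phase label(s): ",
                 paste(setdiff(unique(traces$phase), PHASES), collapse = ", ")),
          "fluxdeconv_format_error")
  if (any(traces$O2_mmHg < 0))
    abort("negative O2 tension in trace", "fluxdeconv_data_error")
  for (w in unique(traces$well)) {
    t <- traces$time_min[traces$well == w]
    if (any(diff(t) <= 0))
      abort(sprintf("non-monotone time in well %s", normalize_well(w)),
            "fluxdeconv_data_error")
  }
  invisible(TRUE)
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf(
    "<plate_run> %d wells, %d cycles, %d samples%s\n",
    length(unique(x$traces$well)), x$n_cycles, nrow(x$traces),
    if (is.null(x$schedule)) "" else
      paste0("; injections: ",
             paste(sprintf("%s@%d", x$schedule$agent, x$schedule$cycle),
                   collapse = ", "))))
  invisible(x)
}

#' Read a plate run from a long-format CSV
#'
#' Expected columns: `well`, `time_min`, `cycle`, `phase`, `O2_mmHg`, `pH`
#' (comma-delimited, header row, "." decimal separator).  Well IDs are
#' case-insensitive on read and normalised to uppercase.
#'
#' @param path CSV file path.
#' @param layout a [plate_layout()] describing the plate.
#' @param schedule optional [injection_schedule()].
#' @return A [plate_run()].
#' @export
load_plate_run <- function(path, layout, schedule = NULL) {
  traces <- read.csv(path, stringsAsFactors = FALSE)
  plate_run(traces, layout, schedule)
}

#' Write a plate run to CSV
#'
#' @param run a [plate_run()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_run <- function(run, path) {
  write.csv(run$traces[, TRACE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Extract one well's level trace
#'
#' @param run a [plate_run()].
#' @param well well ID.
#' @return Data frame of that well's samples, time-ordered.
#' @export
well_trace <- function(run, well) {
  well <- normalize_well(well)
  tr <- run$traces[run$traces$well == well, , drop = FALSE]
  if (nrow(tr) == 0)
    abort(sprintf("no trace for well %s", well), "fluxdeconv_layout_error")
  rownames(tr) <- NULL
  tr
}

## ---- Clark-electrode traces ------------------------------------------------

#' Construct a closed-chamber (Clark electrode) trace
#'
#' @param samples data frame with columns `time_min`, `O2_nmol_per_mL`.
#' @param volume_mL chamber volume in mL (1.5 mL water-jacketed cell in the
#'   reference setup).
#' @param n_embryos embryos in the chamber.
#' @return A `clark_trace` object.
#' @export
clark_trace <- function(samples, volume_mL, n_embryos) {
  if (volume_mL <= 0)
    abort("chamber volume must be positive", "fluxdeconv_config_error")
  if (n_embryos < 1)
    abort("a Clark run needs at least one embryo", "fluxdeconv_config_error")
  miss <- setdiff(c("time_min", "O2_nmol_per_mL"), names(samples))
  if (length(miss) > 0)
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          "fluxdeconv_format_error")
  if (any(diff(samples$time_min) <= 0))
    abort("non-monotone time in Clark trace", "fluxdeconv_data_error")
  structure(list(samples = samples, volume_mL = volume_mL,
                 n_embryos = n_embryos),
            class = "clark_trace")
}

#' Read a Clark-electrode trace from a two-column CSV
#'
#' @param path CSV with columns `time_min`, `O2_nmol_per_mL`.
#' @inheritParams clark_trace
#' @return A [clark_trace()].
#' @export
load_clark_trace <- function(path, volume_mL, n_embryos) {
  clark_trace(read.csv(path, stringsAsFactors = FALSE), volume_mL, n_embryos)
}

#' @export
print.clark_trace <- function(x, ...) {
  cat(sprintf("<clark_trace> %g mL chamber, %d embryo(s), %d samples\n",
              x$volume_mL, x$n_embryos, nrow(x$samples)))
  invisible(x)
}
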