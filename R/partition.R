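## Five-way deconvolution of basal respiration.  With R_basal the
## pre-injection rate, R_oligo the post-oligomycin minimum, R_azide the
## post-azide minimum and R_fccp the post-uncoupler maximum:
##
##   mitochondrial respiration   R_mito    = R_basal - R_azide
##   ATP-turnover-linked         R_atp     = R_basal - R_oligo
##   proton leak                 R_leak    = R_oligo - R_azide
##   non-mitochondrial           R_nonmito = R_azide
##   maximal uncoupled capacity  R_maxunc  = R_fccp  - R_azide
##
## so R_mito = R_atp + R_leak and the nonmito/ATP/leak fractions of basal
## sum to 1 exactly.  Negative components are retained and flagged, never
## clipped: "not different from zero" must stay testable.

#' Total basal respiration from per-cycle rates
#'
#' The basal rate is the mean of measurement cycles 5 and 6.  If either is
#' QC-invalid, the latest two consecutive valid basal cycles are used
#' instead, with a warning.
#'
#' @param cycle_rates one well's `cycle_rates` rows (see [estimate_ocr()]),
#'   or a bare numeric vector of basal-cycle rates (cycle 1 first).
#' @param n_basal number of basal cycles preceding the first injection
#'   (default 6); at least this many basal cycles must be present.
#' @param column rate column to average (`"ocr_pmol_min"` or
#'   `"ecar_mpH_min"`).
#' @return Basal rate, with attribute `cycles` naming the two cycles used.
#' @export
basal_rate <- function(cycle_rates, n_basal = 6L, column = "ocr_pmol_min") {
  if (is.numeric(cycle_rates)) {
    cycle_rates <- data.frame(cycle = seq_along(cycle_rates),
                              rate = cycle_rates, valid = TRUE)
  } else {
    cycle_rates <- data.frame(cycle = cycle_rates$cycle,
                              rate = cycle_rates[[column]],
                              valid = cycle_rates$valid)
  }
  basal <- cycle_rates[cycle_rates$cycle <= n_basal, , drop = FALSE]
  if (nrow(basal) < n_basal)
    abort(sprintf("need %d basal cycles, found %d", n_basal, nrow(basal)),
          "fluxdeconv_input_error")
  basal <- basal[order(basal$cycle), ]
  pick <- basal[basal$cycle %in% c(n_basal - 1L, n_basal), ]
  if (nrow(pick) == 2 && all(pick$valid)) {
    return(structure(mean(pick$rate), cycles = pick$cycle))
  }
  ## fall back to the latest consecutive valid pair among basal cycles
  ok <- which(basal$valid)
  pairs <- ok[which(diff(ok) == 1)]
  if (length(pairs) == 0)
    abort("no two consecutive valid basal cycles", "fluxdeconv_qc_error")
  i <- max(pairs)
  warning(sprintf(
    "basal cycles %d/%d unusable; using cycles %d and %d instead",
    n_basal - 1L, n_basal, basal$cycle[i], basal$cycle[i + 1L]))
  structure(mean(basal$rate[c(i, i + 1L)]),
            cycles = basal$cycle[c(i, i + 1L)])
}

#' Treatment rate from post-injection cycles
#'
#' Locates the extreme post-injection cycle (maximum after an uncoupler,
#' minimum after oligomycin or azide), pairs it with whichever adjacent
#' cycle gives the more extreme two-cycle mean (earlier pair on ties), and
#' returns that mean.
#'
#' @param cycle_rates the post-injection window: `cycle_rates` rows or a
#'   numeric vector in cycle order.
#' @param direction `"max"` (uncoupler) or `"min"` (inhibitors).
#' @param column rate column, as in [basal_rate()].
#' @return Treatment rate, with attribute `cycles` naming the pair used.
#' @export
treatment_rate <- function(cycle_rates, direction = c("min", "max"),
                           column = "ocr_pmol_min") {
  direction <- match.arg(direction)
  if (is.numeric(cycle_rates)) {
    rates <- cycle_rates
    cycles <- seq_along(cycle_rates)
  } else {
    keep <- cycle_rates$valid
    rates <- cycle_rates[[column]][keep]
    cycles <- cycle_rates$cycle[keep]
  }
  n <- length(rates)
  if (n < 2)
    abort("need at least 2 valid post-injection cycles",
          "fluxdeconv_input_error")
  ext <- if (direction == "max") which.max(rates) else which.min(rates)
  cand <- list()
  if (ext > 1) cand <- c(cand, list(c(ext - 1L, ext)))
  if (ext < n) cand <- c(cand, list(c(ext, ext + 1L)))
  means <- vapply(cand, function(p) mean(rates[p]), 0)
  best <- if (direction == "max") which.max(means) else which.min(means)
  ## which.max/min return the first (earlier) index on exact ties
  structure(means[best], cycles = cycles[cand[[best]]])
}

#' Extract basal and per-agent treatment rates for every well
#'
#' Applies [basal_rate()] to the basal cycles and [treatment_rate()] to
#' each injection window (bounded by the next injection) of every well.
#' Treatment ECARs are averaged over the same cycle pair at which the
#' extreme OCR was found.
#'
#' @param cycle_rates a `cycle_rates` data frame (all wells).
#' @param schedule the run's [injection_schedule()].
#' @param n_cycles total cycles in the run.
#' @param n_basal basal cycles before the first injection.
#' @return Data frame: `well`, `ocr_basal`, `ecar_basal`, then
#'   `ocr_<agent>` / `ecar_<agent>` per scheduled agent.
#' @export
extract_phase_rates <- function(cycle_rates, schedule,
                                n_cycles = max(cycle_rates$cycle),
                                n_basal = 6L) {
  windows <- schedule_windows(schedule, n_cycles)
  wells <- unique(cycle_rates$well)
  rows <- lapply(wells, function(w) {
    cr <- cycle_rates[cycle_rates$well == w, , drop = FALSE]
    b_ocr <- basal_rate(cr, n_basal = n_basal)
    row <- data.frame(well = w, ocr_basal = as.numeric(b_ocr),
                      ecar_basal = NA_real_, stringsAsFactors = FALSE)
    bcyc <- attr(b_ocr, "cycles")
    row$ecar_basal <- mean(cr$ecar_mpH_min[cr$cycle %in% bcyc])
    for (k in seq_len(nrow(windows))) {
      win <- cr[cr$cycle >= windows$from[k] & cr$cycle <= windows$to[k], ]
      tr <- treatment_rate(win, direction = windows$direction[k])
      row[[paste0("ocr_", windows$agent[k])]] <- as.numeric(tr)
      tcyc <- attr(tr, "cycles")
      row[[paste0("ecar_", windows$agent[k])]] <-
        mean(win$ecar_mpH_min[win$cycle %in% tcyc])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition basal respiration into its components
#'
#' @param R_basal,R_oligo,R_azide,R_fccp the four extracted rates
#'   (vectorised; same units, typically pmol O2/min per well).
#' @return A `partition_result` data frame with the four inputs, the five
#'   components (`mito`, `atp`, `leak`, `nonmito`, `maxunc`), the
#'   fraction-of-basal columns (`f_nonmito`, `f_atp`, `f_leak`, summing to
#'   1 exactly) and a `negative_component` flag.  Negative components are
#'   retained, not clipped.
#' @export
partition <- function(R_basal, R_oligo, R_azide, R_fccp) {
  vals <- cbind(R_basal, R_oligo, R_azide, R_fccp)
  if (any(!is.finite(vals)))
    abort("all four rates must be finite", "fluxdeconv_input_error")
  out <- data.frame(
    basal = R_basal, oligo = R_oligo, azide = R_azide, fccp = R_fccp,
    mito = R_basal - R_azide,
    atp = R_basal - R_oligo,
    leak = R_oligo - R_azide,
    nonmito = R_azide,
    maxunc = R_fccp - R_azide
  )
  out$f_nonmito <- out$nonmito / out$basal
  out$f_atp <- out$atp / out$basal
  out$f_leak <- out$leak / out$basal
  out$negative_component <-
    out$mito < 0 | out$atp < 0 | out$leak < 0 | out$nonmito < 0 |
    out$maxunc < 0
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Per-embryo normalization of a partition result
#'
#' Divides every rate column by the embryo count; fractions are scale
#' invariant and untouched.
#'
#' @param result a [partition()] result.
#' @param n_embryos embryos per well (scalar or one per row).
#' @return The result with rate columns per embryo.
#' @export
per_embryo <- function(result, n_embryos) {
  if (any(n_embryos < 1))
    abort("n_embryos must be >= 1", "fluxdeconv_input_error")
  rate_cols <- c("basal", "oligo", "azide", "fccp",
                 "mito", "atp", "leak", "nonmito", "maxunc")
  result[rate_cols] <- result[rate_cols] / n_embryos
  result
}

#' Mitochondrial-content normalization of a partition result
#'
#' Divides the mitochondrial and maximal-uncoupled rates by the stage's
#' COX IV index (per-embryo mitochondrial-content proxy, 3 hpf == 1),
#' adding `mito_coxnorm` and `maxunc_coxnorm` columns.
#'
#' @param result a [partition()] result.
#' @param cox_index positive index for this stage (see [cox_iv_index()]).
#' @return The result with the two normalized columns added.
#' @export
coxiv_normalize <- function(result, cox_index) {
  if (length(cox_index) != 1 || is.na(cox_index) || cox_index <= 0)
    abort("COX IV index must be a single positive value for the stage",
          "fluxdeconv_input_error")
  result$mito_coxnorm <- result$mito / cox_index
  result$maxunc_coxnorm <- result$maxunc / cox_index
  result
}

#' Upper bound on organic-carbon loss from substrate oxidation
#'
#' Under pure carbohydrate oxidation one mole of O2 oxidizes one mole of
#' carbon, so the carbon lost is at most `total_O2_nmol * 12 / 1000`
#' micrograms; lipid oxidation loses less carbon per O2, so this is an
#' upper bound.
#'
#' @param total_O2_nmol cumulative O2 consumed, nmol (per embryo).
#' @return Carbon mass bound, micrograms.
#' @export
carbon_loss_bound <- function(total_O2_nmol) {
  if (any(total_O2_nmol < 0))
    abort("total O2 consumed cannot be negative", "fluxdeconv_input_error")
  total_O2_nmol * 12 / 1000
}

#' Bound on the lactate contribution to acid extrusion
#'
#' If no lactate is detected above the assay's detection limit after
#' incubating embryos in a known media volume, the lactate-attributable PPR
#' is at most `limit * volume / (duration * n_embryos)` (1 H+ per lactate),
#' and its share of the measured PPR is bounded accordingly.
#'
#' @param detection_limit_uM lactate detection limit, umol/L.
#' @param media_volume_mL incubation media volume, mL.
#' @param n_embryos embryos incubated.
#' @param duration_min incubation time, minutes.
#' @param measured_ppr measured PPR, nmol H+/min/embryo (optional).
#' @return List: `max_lactate_ppr` (nmol H+/min/embryo) and `max_fraction`
#'   (`NA` with attribute `undefined = TRUE` when `measured_ppr` is absent
#'   or non-positive).
#' @export
lactate_ppr_bound <- function(detection_limit_uM, media_volume_mL,
                              n_embryos, duration_min,
                              measured_ppr = NULL) {
  if (detection_limit_uM < 0 || media_volume_mL <= 0 || n_embryos < 1 ||
      duration_min <= 0)
    abort("inputs must be positive (detection limit may be zero)",
          "fluxdeconv_input_error")
  ## uM * mL = nmol of lactate in the sampled media
  bound <- detection_limit_uM * media_volume_mL /
    (duration_min * n_embryos)
  if (is.null(measured_ppr) || measured_ppr <= 0) {
    frac <- structure(NA_real_, undefined = TRUE)
  } else {
    frac <- bound / measured_ppr
  }
  list(max_lactate_ppr = bound, max_fraction = frac)
}
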