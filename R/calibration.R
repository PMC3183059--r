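## Buffer capacity, ECAR -> PPR conversion, and Clark-electrode
## cross-calibration of plate-derived OCRs.

#' Buffer capacity from an acid titration
#'
#' The raw titration slope is the negated OLS slope of pH (in mpH) against
#' cumulative protons added to the titrated volume.  The chamber buffer
#' capacity rescales it to the transient microchamber volume, so that
#' dividing a measured ECAR by `bc_chamber` directly yields PPR.
#'
#' @param titration data frame `cumulative_nmol_H`, `pH` (>= 3 rows).
#' @param titrated_volume_uL volume the acid was delivered into (700 uL for
#'   a full well).
#' @param chamber_volume_uL microchamber volume the assay pH is read in.
#' @param warn_tol non-monotonicity tolerance in slope SEs before a
#'   titration-quality warning is emitted.
#' @return A `buffer_capacity` list: `bc_chamber` (mpH/nmol in the
#'   chamber), `raw_slope` (mpH/nmol in the titrated volume),
#'   `titrated_volume_uL`, `chamber_volume_uL`.
#' @export
buffer_capacity <- function(titration, titrated_volume_uL = 700,
                            chamber_volume_uL = 7, warn_tol = 3) {
  miss <- setdiff(c("cumulative_nmol_H", "pH"), names(titration))
  if (length(miss) > 0)
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          "fluxdeconv_format_error")
  if (nrow(titration) < 3)
    abort("need at least 3 titration points", "fluxdeconv_input_error")
  if (titrated_volume_uL <= 0 || chamber_volume_uL <= 0)
    abort("volumes must be positive", "fluxdeconv_config_error")
  fit <- ols_slope(titration$cumulative_nmol_H, 1000 * titration$pH)
  raw <- -fit$slope                            # mpH per nmol, titrated volume
  se <- fit$se
  if (raw <= 0)
    abort("titration slope is not negative: pH must fall as acid is added",
          "fluxdeconv_data_error")
  if (any(diff(titration$pH) > warn_tol * se / 1000))
    warning("non-monotone pH beyond noise tolerance: check titration quality")
  structure(list(bc_chamber = raw * titrated_volume_uL / chamber_volume_uL,
                 raw_slope = raw,
                 titrated_volume_uL = titrated_volume_uL,
                 chamber_volume_uL = chamber_volume_uL),
            class = "buffer_capacity")
}

#' @export
print.buffer_capacity <- function(x, ...) {
  cat(sprintf(
    "<buffer_capacity> %.4g mpH/nmol in chamber (raw %.4g mpH/nmol in %g uL)\n",
    x$bc_chamber, x$raw_slope, x$titrated_volume_uL))
  invisible(x)
}

#' Convert ECAR to proton production rate
#'
#' `PPR = ECAR / bc_chamber`.  Negative ECAR (media alkalinization) is
#' allowed and returns a negative PPR carrying attribute
#' `alkalinization = TRUE`.
#'
#' @param ecar_mpH_min ECAR, mpH/min (vectorised).
#' @param bc a [buffer_capacity()] or a bare chamber buffer capacity in
#'   mpH/nmol.
#' @return PPR in nmol H+/min.
#' @export
ecar_to_ppr <- function(ecar_mpH_min, bc) {
  bcc <- if (inherits(bc, "buffer_capacity")) bc$bc_chamber else bc
  if (!is.numeric(bcc) || bcc <= 0)
    abort("buffer capacity must be positive", "fluxdeconv_config_error")
  ppr <- ecar_mpH_min / bcc
  if (any(ppr < 0, na.rm = TRUE)) attr(ppr, "alkalinization") <- TRUE
  ppr
}

#' Clark-electrode calibration factor for plate OCRs
#'
#' The ratio of mean Clark-electrode respiration to mean plate-derived
#' respiration on matched specimens; applied multiplicatively to all plate
#' OCRs.  Because it is a single positive scale, fraction-of-total
#' partitioning is unchanged by calibration.
#'
#' @param clark_rates,xf_rates per-run rates from each instrument, same
#'   units (e.g. nmol O2/min/embryo); non-empty, positive means.
#' @return A `calibration_factor` list: `factor`, `clark_mean`, `xf_mean`,
#'   `n_clark`, `n_xf`.
#' @export
clark_calibration_factor <- function(clark_rates, xf_rates) {
  if (length(clark_rates) == 0 || length(xf_rates) == 0)
    abort("both rate lists must be non-empty", "fluxdeconv_input_error")
  cm <- mean(clark_rates)
  xm <- mean(xf_rates)
  if (cm <= 0 || xm <= 0)
    abort("instrument mean rates must be positive", "fluxdeconv_data_error")
  structure(list(factor = cm / xm, clark_mean = cm, xf_mean = xm,
                 n_clark = length(clark_rates), n_xf = length(xf_rates)),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf(
    "<calibration_factor> %.4f (Clark %.4g, n=%d / XF %.4g, n=%d)\n",
    x$factor, x$clark_mean, x$n_clark, x$xf_mean, x$n_xf))
  invisible(x)
}

#' Apply a calibration factor to rates
#'
#' @param rates numeric rates, or a `cycle_rates` data frame (the
#'   `ocr_pmol_min` column is scaled).
#' @param factor a [clark_calibration_factor()] or bare positive number.
#' @return Scaled rates, same shape as the input.
#' @export
apply_calibration <- function(rates, factor) {
  f <- if (inherits(factor, "calibration_factor")) factor$factor else factor
  if (!is.numeric(f) || f <= 0)
    abort("calibration factor must be positive", "fluxdeconv_config_error")
  if (inherits(rates, "cycle_rates")) {
    rates$ocr_pmol_min <- rates$ocr_pmol_min * f
    return(rates)
  }
  rates * f
}
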