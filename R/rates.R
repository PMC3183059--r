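## Level-trace -> per-cycle rates.  Two estimators are provided:
##
##  * "slope": OCR from the ordinary least-squares O2 slope over each
##    measure phase, times chamber volume and solubility.  Ignores plate
##    diffusion and atmospheric leak, so it under-reads whenever the chamber
##    is depleted below ambient.
##  * "compartment": fits the same two-compartment model the generator
##    integrates.  The chamber response is linear in OCR (superposition of
##    the zero-consumption path and a unit-consumption response), so the
##    per-cycle fit is exact linear least squares; the wall-compartment
##    state is carried forward between cycles.
##
## ECAR is always the negated OLS pH slope over the measure phase (mpH/min).

measure_samples <- function(trace, cycle) {
  trace[trace$phase == "measure" & trace$cycle == cycle, , drop = FALSE]
}

## slope, R2 and slope SE from an OLS line; R2/SE computed directly so
## noiseless (perfect-fit) traces do not trip summary.lm warnings
ols_slope <- function(x, y) {
  fit <- lm(y ~ x)
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  se <- if (n > 2) sqrt(ss_res / (n - 2) / sum((x - mean(x))^2)) else NA_real_
  list(slope = unname(coef(fit)[2]),
       r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       se = se)
}

#' Coefficient of determination of the measure-phase O2 fit
#'
#' R-squared of the OLS line through the measure-phase O2 samples of one
#' cycle.  A constant trace (zero variance) is a degenerate perfect fit:
#' R-squared is reported as 1 with attribute `degenerate = TRUE`.
#'
#' @param trace one well's level trace (data frame as in [well_trace()]).
#' @param cycle measurement cycle index.
#' @return R-squared in `[0, 1]`, possibly with attribute `degenerate`.
#' @export
linearity_r2 <- function(trace, cycle) {
  m <- measure_samples(trace, cycle)
  if (nrow(m) < 3)
    abort(sprintf("cycle %d has fewer than 3 measure samples", cycle),
          "fluxdeconv_qc_error")
  if (var(m$O2_mmHg) == 0)
    return(structure(1, degenerate = TRUE))
  ols_slope(m$time_min, m$O2_mmHg)$r2
}

#' Hypoxia quality control
#'
#' Embryo counts are chosen so oxygen tension never falls below 100 mmHg
#' during a rate measurement; cycles that do are unusable.
#'
#' @param trace one well's level trace, or a [plate_run()] (checked for
#'   every well).
#' @param floor_mmHg QC floor, mmHg (default 100).
#' @return Data frame `well`, `cycle`, `min_O2`, `pass`.
#' @export
hypoxia_qc <- function(trace, floor_mmHg = 100) {
  if (inherits(trace, "plate_run")) {
    out <- lapply(unique(trace$traces$well),
                  function(w) hypoxia_qc(well_trace(trace, w), floor_mmHg))
    return(do.call(rbind, out))
  }
  m <- trace[trace$phase == "measure", , drop = FALSE]
  agg <- tapply(m$O2_mmHg, m$cycle, min)
  data.frame(well = rep(unique(trace$well), length(agg)),
             cycle = as.integer(names(agg)),
             min_O2 = unname(agg),
             pass = unname(agg) >= floor_mmHg,
             stringsAsFactors = FALSE)
}

## compartment fit for one measure phase: returns fitted OCR and end state.
## y ~ base(t) + ocr * sens(t); exact linear LS in the single parameter.
fit_measure_phase <- function(stepper, x0, times, y) {
  n <- length(times)
  base <- numeric(n)
  sens <- numeric(n)
  xb <- x0
  xs <- c(0, 0)
  base[1] <- xb[1]
  sens[1] <- 0
  for (j in 2:n) {
    dt <- times[j] - times[j - 1]
    p <- stepper$pieces(TRUE, dt)
    xb <- drop(p$Phi %*% xb) + p$psi0
    xs <- drop(p$Phi %*% xs) + p$psi_unit
    base[j] <- xb[1]
    sens[j] <- xs[1]
  }
  denom <- sum(sens^2)
  ocr <- if (denom == 0) 0 else sum(sens * (y - base)) / denom
  ## end state under the fitted OCR (linearity of the propagated state)
  x_end <- xb + ocr * xs
  list(ocr = ocr, x_end = x_end)
}

estimate_ocr_well <- function(trace, physics, method, stepper = NULL) {
  cycles <- sort(unique(trace$cycle))
  if (method == "compartment" && is.null(stepper))
    stepper <- make_stepper(physics)
  scale <- physics$V_ch_uL * physics$k_O2   # pmol per mmHg
  x <- c(physics$O_atm, physics$O_atm)
  t_cur <- 0
  out <- data.frame(well = rep(unique(trace$well), length(cycles)),
                    cycle = cycles, ocr_pmol_min = NA_real_,
                    ecar_mpH_min = NA_real_, r2 = NA_real_,
                    min_O2 = NA_real_, n_measure = NA_integer_,
                    method = method, valid = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cycles)) {
    m <- measure_samples(trace, cycles[i])
    out$n_measure[i] <- nrow(m)
    if (nrow(m) < 3) {
      ## flagged invalid, never silently dropped; wall state coasts open
      next
    }
    out$min_O2[i] <- min(m$O2_mmHg)
    o2fit <- ols_slope(m$time_min, m$O2_mmHg)
    out$r2[i] <- if (var(m$O2_mmHg) == 0) 1 else o2fit$r2
    out$ecar_mpH_min[i] <- -1000 * ols_slope(m$time_min, m$pH)$slope
    if (method == "slope") {
      out$ocr_pmol_min[i] <- -o2fit$slope * scale
    } else {
      x <- stepper$advance(x, m$time_min[1] - t_cur, closed = FALSE)
      x[1] <- m$O2_mmHg[1]   # anchor the chamber to the observed level
      fit <- fit_measure_phase(stepper, x, m$time_min, m$O2_mmHg)
      out$ocr_pmol_min[i] <- fit$ocr
      x <- fit$x_end
      t_cur <- m$time_min[nrow(m)]
    }
    out$valid[i] <- TRUE
  }
  out
}

#' Estimate per-cycle OCR and ECAR from level traces
#'
#' @param trace one well's level trace, or a [plate_run()] (all wells).
#' @param physics [chamber_physics()]; the compartment method uses the
#'   diffusion/leak constants, the slope method only volume and solubility.
#' @param method `"compartment"` (default, diffusion-aware) or `"slope"`.
#' @return A `cycle_rates` data frame: `well`, `cycle`, `ocr_pmol_min`,
#'   `ecar_mpH_min`, `r2`, `min_O2`, `n_measure`, `method`, `valid`.
#'   Cycles with fewer than 3 measure samples are flagged invalid
#'   (`valid = FALSE`, rates `NA`).
#' @export
estimate_ocr <- function(trace, physics = chamber_physics(),
                         method = c("compartment", "slope")) {
  method <- match.arg(method)
  if (inherits(trace, "plate_run")) {
    stepper <- if (method == "compartment") make_stepper(physics) else NULL
    out <- lapply(unique(trace$traces$well), function(w)
      estimate_ocr_well(well_trace(trace, w), physics, method, stepper))
    res <- do.call(rbind, out)
  } else {
    res <- estimate_ocr_well(trace, physics, method)
  }
  rownames(res) <- NULL
  class(res) <- c("cycle_rates", "data.frame")
  res
}

#' OCR from a closed-chamber Clark-electrode trace
#'
#' The closed cell loses dissolved O2 linearly; OCR per embryo is the
#' negated OLS concentration slope times chamber volume over embryo count.
#'
#' @param trace a [clark_trace()].
#' @param slope_tol positive-slope tolerance in slope SEs: a fitted slope
#'   more than this many SEs above zero is a data error (a closed chamber
#'   cannot gain O2).
#' @return OCR in nmol O2/min/embryo, with attributes `slope`
#'   (nmol/mL/min) and `slope_se`.
#' @export
clark_ocr <- function(trace, slope_tol = 3) {
  s <- trace$samples
  if (nrow(s) < 3)
    abort("need at least 3 Clark samples", "fluxdeconv_input_error")
  fit <- ols_slope(s$time_min, s$O2_nmol_per_mL)
  slope <- fit$slope
  se <- fit$se
  if (slope > slope_tol * se && slope > 0)
    abort("O2 concentration rises in a closed chamber: bad trace",
          "fluxdeconv_data_error")
  structure(-slope * trace$volume_mL / trace$n_embryos,
            slope = slope, slope_se = se)
}
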