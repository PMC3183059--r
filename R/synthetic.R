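## Ground-truthed synthetic assay data.  The generator emulates the study
## conditions of a developmental respirometry run: six basal measurement
## cycles, then oligomycin / FCCP / azide injections with 18 further cycles;
## microchamber O2 depletion with plate diffusion and atmospheric leak;
## basal OCR and PPR rising linearly with stage; lognormal well-to-well and
## clutch-to-clutch variation plus additive sensor noise.

#' Ground-truth stage parameters for the synthetic generator
#'
#' @param hpf stage, hours post-fertilization.
#' @param ocr_per_embryo true basal OCR, pmol O2/min/embryo.
#' @param f_nonmito,f_leak fractions of total basal respiration that are
#'   non-mitochondrial and proton-leak-linked; the ATP-turnover fraction is
#'   the remainder, so the three always sum to 1 by construction.
#' @param fccp_fold uncoupled respiration as a multiple of basal
#'   mitochondrial respiration.
#' @param ppr_per_embryo true basal PPR, nmol H+/min/embryo.
#' @param well_cv,clutch_cv lognormal coefficients of variation of the
#'   well-level and plate-level (clutch) rate multipliers.
#' @param ppr_oligo_factor,ppr_fccp_factor,ppr_azide_factor PPR multipliers
#'   in force after each agent class.
#' @return A `stage_params` list.
#' @export
stage_params <- function(hpf, ocr_per_embryo, f_nonmito, f_leak, fccp_fold,
                         ppr_per_embryo, well_cv = 0.10, clutch_cv = 0.10,
                         ppr_oligo_factor = 0.9, ppr_fccp_factor = 1.5,
                         ppr_azide_factor = 0.2) {
  f_atp <- 1 - f_nonmito - f_leak
  fr <- c(f_nonmito = f_nonmito, f_leak = f_leak, f_atp = f_atp)
  if (any(fr < 0) || any(fr > 1))
    abort("partition fractions must lie in [0, 1] and sum to 1",
          "fluxdeconv_config_error")
  if (ocr_per_embryo <= 0 || ppr_per_embryo <= 0)
    abort("true basal OCR and PPR must be positive",
          "fluxdeconv_config_error")
  if (well_cv < 0 || clutch_cv < 0)
    abort("noise CVs must be non-negative", "fluxdeconv_config_error")
  if (fccp_fold <= 0)
    abort("FCCP fold-increase must be positive", "fluxdeconv_config_error")
  structure(list(hpf = hpf, ocr_per_embryo = ocr_per_embryo,
                 f_nonmito = f_nonmito, f_leak = f_leak, f_atp = f_atp,
                 fccp_fold = fccp_fold, ppr_per_embryo = ppr_per_embryo,
                 well_cv = well_cv, clutch_cv = clutch_cv,
                 ppr_oligo_factor = ppr_oligo_factor,
                 ppr_fccp_factor = ppr_fccp_factor,
                 ppr_azide_factor = ppr_azide_factor),
            class = "stage_params")
}

#' Default ground-truth table for the six assayed stages
#'
#' Basal OCR per embryo rises linearly with age, anchored at 91 pmol/min at
#' 30 hpf (the Clark-electrode benchmark) with ~15 pmol/min at 3 hpf.
#' Proton-leak fractions are 0 at 3 and 7 hpf, 27% at 12 and 24 hpf, 18% at
#' 30 hpf and 9.4% at 48 hpf; the non-mitochondrial fraction is highest at
#' 3 hpf and flat from 12 hpf on; the FCCP response peaks at 7 hpf.  Basal
#' PPR rises linearly to 1 nmol H+/min/embryo at 30 hpf.
#'
#' @param overrides optional named list `hpf -> list(field = value, ...)`
#'   patching individual stages.
#' @return Named list of [stage_params()], one per stage, names = hpf.
#' @export
default_stage_table <- function(overrides = NULL) {
  hpf <- assayed_stages()
  ocr_slope <- (91 - 15) / (30 - 3)
  ocr_int <- 15 - 3 * ocr_slope
  ppr_slope <- (1.0 - 0.2) / (30 - 3)
  ppr_int <- 0.2 - 3 * ppr_slope
  f_leak <- c(0, 0, 0.27, 0.27, 0.18, 0.094)
  f_nonmito <- c(0.55, 0.40, 0.30, 0.30, 0.30, 0.30)
  fccp_fold <- c(1.5, 1.9, 1.7, 1.6, 1.4, 1.2)
  tab <- lapply(seq_along(hpf), function(i) {
    args <- list(hpf = hpf[i],
                 ocr_per_embryo = ocr_int + ocr_slope * hpf[i],
                 f_nonmito = f_nonmito[i], f_leak = f_leak[i],
                 fccp_fold = fccp_fold[i],
                 ppr_per_embryo = ppr_int + ppr_slope * hpf[i])
    ov <- overrides[[as.character(hpf[i])]]
    if (!is.null(ov)) args[names(ov)] <- ov
    do.call(stage_params, args)
  })
  names(tab) <- as.character(hpf)
  tab
}

## true rate multiplier for the agent in force (NA = basal)
ocr_agent_factor <- function(params, agent) {
  if (is.na(agent)) return(1)
  switch(agent,
         oligomycin = params$f_nonmito + params$f_leak,
         fccp = , dnp =
           params$f_nonmito + params$fccp_fold * (1 - params$f_nonmito),
         azide = , rotenone = , antimycin = params$f_nonmito,
         abort(paste0("no true-rate rule for agent ", agent),
               "fluxdeconv_schedule_error"))
}

ppr_agent_factor <- function(params, agent) {
  if (is.na(agent)) return(1)
  switch(agent,
         oligomycin = params$ppr_oligo_factor,
         fccp = , dnp = params$ppr_fccp_factor,
         azide = , rotenone = , antimycin = params$ppr_azide_factor)
}

lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## within-cycle sample offsets (minutes): open phases sparsely, measure
## phase densely; offsets tile the 4.5 min cycle without duplicating the
## cycle boundary
open_offsets <- function() seq(0.25, 2.75, by = 0.25)
measure_offsets <- function() seq(3, 4.5, by = 0.15)

#' Simulate a full plate run with known ground truth
#'
#' Integrates the two-compartment chamber model (exactly, via the matrix
#' exponential) for every well through 6 basal and 18 post-injection
#' measurement cycles, switching the true consumption rate as each agent is
#' injected, and overlays lognormal well/clutch rate multipliers and
#' Gaussian sensor noise.
#'
#' @param stage_hpf one of the assayed stages.
#' @param layout plate layout; defaults to the stage's islet layout.
#' @param schedule injection schedule; defaults to [default_schedule()].
#'   `NULL` schedule gives a basal-only run.
#' @param physics [chamber_physics()].
#' @param params [stage_params()] ground truth; defaults to
#'   [default_stage_table()] for the stage.
#' @param seed integer seed; identical seeds give bit-identical runs.
#' @param n_cycles total measurement cycles (default 24).
#' @param o2_sd,ph_sd additive sensor noise SD (mmHg, pH units).
#' @param noise set `FALSE` to zero every noise source (sensor noise and
#'   both CVs) regardless of the other arguments.
#' @return List with `run` (a [plate_run()]) and `truth` (ground-truth
#'   record: stage parameters, clutch multiplier, per-well multipliers and
#'   true OCR/PPR per injection window).
#' @export
simulate_plate <- function(stage_hpf, layout = NULL, schedule = default_schedule(stage_hpf),
                           physics = chamber_physics(), params = NULL,
                           seed = 1L, n_cycles = 24L,
                           o2_sd = 0.2, ph_sd = 5e-4, noise = TRUE) {
  if (is.null(layout)) layout <- plate_layout(stage_hpf)
  issues <- validate_layout(layout)
  if (length(issues) > 0)
    abort(paste0("invalid layout: ", paste(issues, collapse = "; ")),
          "fluxdeconv_layout_error")
  if (!is.null(schedule) && any(schedule$cycle > n_cycles))
    abort("injection scheduled beyond the last cycle",
          "fluxdeconv_schedule_error")
  if (is.null(params)) params <- default_stage_table()[[as.character(stage_hpf)]]
  if (!noise) {
    o2_sd <- 0
    ph_sd <- 0
    params$well_cv <- 0
    params$clutch_cv <- 0
  }
  set.seed(as.integer(seed))
  clutch_mult <- lognorm_mult(1, params$clutch_cv)
  well_mult <- setNames(lognorm_mult(24, params$well_cv), plate_wells())

  stepper <- make_stepper(physics)
  t_open <- open_offsets()
  t_meas <- measure_offsets()
  dt_open <- diff(c(0, t_open, 3))       # includes final step to sensor-down
  dt_meas <- diff(t_meas)
  n_per_cycle <- length(t_open) + length(t_meas)

  traces <- vector("list", 24)
  truth_rows <- vector("list", 24)
  for (wi in seq_len(24)) {
    w <- plate_wells()[wi]
    lrow <- layout[normalize_well(layout$well) == w, ]
    n_emb <- lrow$n_embryos
    mult <- clutch_mult * well_mult[[w]]
    ocr_basal <- params$ocr_per_embryo * n_emb * mult
    ppr_basal <- params$ppr_per_embryo * n_emb * mult

    x <- c(physics$O_atm, physics$O_atm)   # chamber, wall
    pH <- physics$pH0
    times <- o2 <- ph <- numeric(n_cycles * n_per_cycle)
    cyc <- integer(n_cycles * n_per_cycle)
    phs <- character(n_cycles * n_per_cycle)
    k <- 0L
    for (cycle in seq_len(n_cycles)) {
      agent <- if (is.null(schedule)) NA_character_ else
        agent_at_cycle(schedule, cycle)
      ocr_w <- ocr_basal * ocr_agent_factor(params, agent)
      ppr_w <- ppr_basal * ppr_agent_factor(params, agent)
      t0 <- (cycle - 1) * CYCLE_MINUTES
      ## open phases (mix 0-2, wait 2-3): chamber tracks bulk
      for (i in seq_along(t_open)) {
        x <- stepper$advance(x, dt_open[i], closed = FALSE)
        pH <- physics$pH0 + (pH - physics$pH0) * exp(-physics$k_mix * dt_open[i])
        k <- k + 1L
        times[k] <- t0 + t_open[i]
        o2[k] <- x[1]
        ph[k] <- pH
        cyc[k] <- cycle
        phs[k] <- if (t_open[i] < CYCLE_TEMPLATE[["mix"]]) "mix" else "wait"
      }
      ## final open step to the sensor-down instant (t = 3.0)
      x <- stepper$advance(x, dt_open[length(dt_open)], closed = FALSE)
      pH <- physics$pH0 +
        (pH - physics$pH0) * exp(-physics$k_mix * dt_open[length(dt_open)])
      ## measure phase: closed chamber, linear acidification
      for (i in seq_along(t_meas)) {
        if (i > 1) {
          x <- stepper$advance(x, dt_meas[i - 1], closed = TRUE, ocr = ocr_w)
          pH <- pH - ppr_w * physics$bc_chamber / 1000 * dt_meas[i - 1]
        }
        k <- k + 1L
        times[k] <- t0 + t_meas[i]
        o2[k] <- x[1]
        ph[k] <- pH
        cyc[k] <- cycle
        phs[k] <- "measure"
      }
    }
    traces[[wi]] <- data.frame(
      well = w, time_min = times, cycle = cyc, phase = phs,
      O2_mmHg = pmax(0, o2 + rnorm(length(o2), 0, o2_sd)),
      pH = ph + rnorm(length(ph), 0, ph_sd),
      stringsAsFactors = FALSE
    )
    agents <- if (is.null(schedule)) character(0) else schedule$agent
    truth_rows[[wi]] <- data.frame(
      well = w, n_embryos = n_emb, well_mult = unname(well_mult[[w]]),
      window = c("basal", agents),
      ocr_true = ocr_basal * unname(vapply(c(NA_character_, agents),
                                           ocr_agent_factor, 0,
                                           params = params)),
      ppr_true = ppr_basal * unname(vapply(c(NA_character_, agents),
                                           ppr_agent_factor, 0,
                                           params = params)),
      stringsAsFactors = FALSE
    )
  }
  run <- plate_run(do.call(rbind, traces), layout, schedule,
                   n_cycles = n_cycles)
  truth <- list(params = params, clutch_mult = clutch_mult,
                rates = do.call(rbind, truth_rows))
  rownames(truth$rates) <- NULL
  list(run = run, truth = truth)
}

#' Simulate a closed-chamber (Clark electrode) trace
#'
#' A closed respirometry cell: dissolved O2 falls linearly at
#' `n_embryos * ocr / volume`, plus Gaussian sensor noise.
#'
#' @param true_ocr_per_embryo true OCR, pmol O2/min/embryo.
#' @param n_embryos embryos in the chamber.
#' @param volume_mL chamber volume, mL.
#' @param seed integer seed.
#' @param duration_min recording length, minutes.
#' @param dt_min sampling interval, minutes.
#' @param noise_sd sensor noise SD, nmol/mL.
#' @param O2_start starting dissolved O2, nmol/mL (air-saturated fresh water
#'   at 28.5 C is about 244).
#' @return A [clark_trace()].
#' @export
simulate_clark_run <- function(true_ocr_per_embryo, n_embryos, volume_mL,
                               seed = 1L, duration_min = 30, dt_min = 0.5,
                               noise_sd = 0.2, O2_start = 244) {
  if (volume_mL <= 0)
    abort("chamber volume must be positive", "fluxdeconv_config_error")
  if (true_ocr_per_embryo <= 0 || n_embryos < 1)
    abort("OCR and embryo count must be positive", "fluxdeconv_config_error")
  set.seed(as.integer(seed))
  t <- seq(0, duration_min, by = dt_min)
  slope <- n_embryos * true_ocr_per_embryo / 1000 / volume_mL  # nmol/mL/min
  conc <- O2_start - slope * t + rnorm(length(t), 0, noise_sd)
  clark_trace(data.frame(time_min = t, O2_nmol_per_mL = conc),
              volume_mL, n_embryos)
}

#' Simulate an inhibitor titration curve
#'
#' Hill-shaped saturating response of |delta OCR| to dose, with wells above
#' a death-threshold dose flagged dead.  FCCP defaults reproduce the
#' titration outcome at early stages: the strongest non-lethal response sits
#' at 1.875 uM for stages up to 12 hpf and 2.5 uM later.
#'
#' @param agent agent label (see [injection_schedule()] for recognised ones).
#' @param stage_hpf one of the assayed stages.
#' @param doses positive, increasing dose vector (agent units).
#' @param seed integer seed.
#' @param r_max plateau |delta OCR|, pmol/min.
#' @param ec50,hill Hill parameters; defaults depend on agent and stage.
#' @param death_above doses above this are lethal in the assay window.
#' @param noise_cv multiplicative response noise CV.
#' @return A `titration_curve` data frame: `dose`, `response`, `dead`.
#' @export
simulate_titration <- function(agent, stage_hpf, doses, seed = 1L,
                               r_max = 40, ec50 = NULL, hill = 2,
                               death_above = NULL, noise_cv = 0.05) {
  if (length(doses) == 0)
    abort("empty dose list", "fluxdeconv_input_error")
  if (any(doses < 0) || any(diff(doses) <= 0))
    abort("doses must be non-negative and increasing",
          "fluxdeconv_input_error")
  key <- agent_key(agent)
  early <- stage_hpf <= 12
  if (is.null(ec50))
    ec50 <- switch(key, fccp = , dnp = if (early) 0.5 else 0.8,
                   oligomycin = 2, 1)
  if (is.null(death_above))
    death_above <- switch(key, fccp = , dnp = if (early) 2 else 3,
                          oligomycin = 50, 10)
  set.seed(as.integer(seed))
  resp <- r_max * doses^hill / (ec50^hill + doses^hill)
  resp <- resp * lognorm_mult(length(doses), noise_cv)
  resp[doses == 0] <- 0
  curve <- data.frame(dose = doses, response = resp,
                      dead = doses > death_above,
                      agent = key, stage_hpf = stage_hpf,
                      stringsAsFactors = FALSE)
  class(curve) <- c("titration_curve", "data.frame")
  curve
}

#' Simulate a buffer-capacity titration
#'
#' Known quantities of protons (0.1 N HCl additions) are delivered into the
#' running media and pH recorded after each addition:
#' `pH_k = pH0 - bc_true * k * nmol_per_addition / 1000 + noise`.
#'
#' @param bc_true true buffer capacity of the titrated volume, mpH/nmol.
#' @param volume_uL titrated volume (700 uL full well by default).
#' @param n_additions acid additions after the baseline reading (>= 2).
#' @param nmol_per_addition protons per addition, nmol (100 nmol = 1 uL of
#'   0.1 N HCl).
#' @param seed integer seed.
#' @param noise_sd_mpH pH-read noise SD in mpH.
#' @param pH0 starting pH.
#' @return Data frame `cumulative_nmol_H`, `pH` with `n_additions + 1` rows.
#' @export
simulate_buffer_titration <- function(bc_true, volume_uL = 700,
                                      n_additions = 5,
                                      nmol_per_addition = 100, seed = 1L,
                                      noise_sd_mpH = 0.5, pH0 = 7.4) {
  if (n_additions < 2)
    abort("need at least 2 acid additions", "fluxdeconv_input_error")
  set.seed(as.integer(seed))
  cum <- (0:n_additions) * nmol_per_addition
  pH <- pH0 - bc_true * cum / 1000 +
    rnorm(length(cum), 0, noise_sd_mpH / 1000)
  data.frame(cumulative_nmol_H = cum, pH = pH)
}
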