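## End-to-end orchestration: simulate (or load) plates per stage, estimate
## per-cycle rates, calibrate, extract basal/treatment rates, partition,
## normalize, and run the cross-stage statistics, into one reproducible
## developmental-profile report.

#' Assemble a pipeline run configuration
#'
#' Every stochastic step derives its seed from `seed` (stage i uses
#' `seed + i - 1`), so a configuration fully determines the output.
#'
#' @param stages stages to profile (default all six).
#' @param seed base integer seed.
#' @param physics [chamber_physics()].
#' @param stage_table ground-truth table for the generator
#'   ([default_stage_table()]).
#' @param method rate estimator, `"compartment"` or `"slope"`.
#' @param noise logical; `FALSE` gives a noiseless in-silico run.
#' @param clark_rates,xf_rates optional matched instrument rates from which
#'   a calibration factor is computed; both `NULL` means factor 1.
#' @param cox_index named per-stage mitochondrial-content index
#'   ([cox_iv_index()]).
#' @param qc_floor_mmHg hypoxia QC floor.
#' @param qc_max_fail lethal fraction of failing sample wells per stage
#'   before the run aborts.
#' @param alpha significance level for the cross-stage comparisons.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = assayed_stages(), seed = 1L,
                       physics = chamber_physics(),
                       stage_table = default_stage_table(),
                       method = c("compartment", "slope"),
                       noise = TRUE,
                       clark_rates = NULL, xf_rates = NULL,
                       cox_index = cox_iv_index(),
                       qc_floor_mmHg = 100, qc_max_fail = 0.5,
                       alpha = 0.05) {
  bad <- setdiff(stages, assayed_stages())
  if (length(bad) > 0)
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          "fluxdeconv_stage_error")
  cfg <- list(stages = as.integer(stages), seed = as.integer(seed),
              physics = physics,
              stage_table = stage_table, method = match.arg(method),
              noise = noise, clark_rates = clark_rates,
              xf_rates = xf_rates, cox_index = cox_index,
              qc_floor_mmHg = qc_floor_mmHg, qc_max_fail = qc_max_fail,
              alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' Round-trips losslessly: `load_run_config(save_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` / the restored `run_config`.
#' @export
save_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$physics <- unclass(plain$physics)
  plain$stage_table <- lapply(plain$stage_table, unclass)
  plain$cox_index <- as.list(plain$cox_index)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$physics <- do.call(chamber_physics, plain$physics)
  plain$stage_table <- lapply(plain$stage_table, function(p)
    do.call(stage_params, p[setdiff(names(p), "f_atp")]))
  plain$cox_index <- unlist(plain$cox_index)
  plain$stages <- as.integer(unlist(plain$stages))
  do.call(run_config, plain)
}

#' Run the full profiling pipeline
#'
#' For each configured stage: simulate an islet plate, estimate per-cycle
#' OCR/ECAR, apply hypoxia QC and Clark calibration, extract basal and
#' treatment rates, partition respiration, normalize per embryo (and by
#' mitochondrial content), and convert basal ECAR to PPR.  Across stages:
#' ANOVA + SNK on the partition fractions, per-stage t tests of the leak
#' fraction against zero, and the linear development trend of basal OCR
#' and PPR.
#'
#' @param config a [run_config()].
#' @return A `flux_report`: `wells` (per-well tidy table), `stage_summary`
#'   (per-stage mean/SEM/n), `comparisons` (SNK on the fractions),
#'   `leak_vs_zero` (per-stage t tests), `trend` (development fits),
#'   `calibration`, and the echoed `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  factor <- if (!is.null(config$clark_rates) && !is.null(config$xf_rates))
    clark_calibration_factor(config$clark_rates, config$xf_rates)$factor
  else 1
  well_tabs <- list()
  for (i in seq_along(config$stages)) {
    hpf <- config$stages[i]
    stage_seed <- config$seed + i - 1L
    well_tabs[[i]] <- profile_stage(hpf, config, stage_seed, factor)
  }
  wells <- do.call(rbind, well_tabs)
  rownames(wells) <- NULL

  agg_cols <- c("ocr_basal_pe", "ppr_basal_pe", "mito_pe", "atp_pe",
                "leak_pe", "nonmito_pe", "maxunc_pe",
                "f_nonmito", "f_atp", "f_leak",
                "mito_coxnorm_pe", "maxunc_coxnorm_pe")
  stage_summary <- do.call(rbind, lapply(split(wells, wells$stage_hpf),
    function(d) {
      out <- data.frame(stage_hpf = d$stage_hpf[1], n_wells = nrow(d))
      for (cc in agg_cols) {
        out[[paste0(cc, "_mean")]] <- mean(d[[cc]])
        out[[paste0(cc, "_sem")]] <- sd(d[[cc]]) / sqrt(nrow(d))
      }
      out
    }))
  stage_summary <- stage_summary[order(stage_summary$stage_hpf), ]
  rownames(stage_summary) <- NULL

  comparisons <- leak_tests <- NULL
  if (length(config$stages) >= 2) {
    grp <- function(col) split(wells[[col]], wells$stage_hpf)
    comparisons <- list(
      f_leak = anova_snk(grp("f_leak"), alpha = config$alpha),
      f_nonmito = anova_snk(grp("f_nonmito"), alpha = config$alpha),
      f_atp = anova_snk(grp("f_atp"), alpha = config$alpha)
    )
  }
  leak_tests <- lapply(split(wells$f_leak, wells$stage_hpf), function(v) {
    if (var(v) == 0) return(NULL)
    t_test_vs_zero(v, alpha = config$alpha)
  })

  trend <- NULL
  if (length(config$stages) >= 3) {
    ocr_means <- stage_summary$ocr_basal_pe_mean
    ppr_means <- stage_summary$ppr_basal_pe_mean
    trend <- list(
      ocr = fit_development_trend(data.frame(
        hpf = stage_summary$stage_hpf, rate = ocr_means)),
      ppr = fit_development_trend(data.frame(
        hpf = stage_summary$stage_hpf, rate = ppr_means))
    )
  }

  structure(list(wells = wells, stage_summary = stage_summary,
                 comparisons = comparisons, leak_vs_zero = leak_tests,
                 trend = trend, calibration_factor = factor,
                 config = config),
            class = "flux_report")
}

profile_stage <- function(hpf, config, stage_seed, factor) {
  params <- config$stage_table[[as.character(hpf)]]
  schedule <- default_schedule(hpf)
  sim <- simulate_plate(hpf, schedule = schedule,
                        physics = config$physics, params = params,
                        seed = stage_seed, noise = config$noise)
  rates <- estimate_ocr(sim$run, config$physics, method = config$method)

  qc <- hypoxia_qc(sim$run, config$qc_floor_mmHg)
  sample_wells <- sim$run$layout$well[sim$run$layout$role == "sample"]
  fail_wells <- unique(qc$well[!qc$pass])
  fail_frac <- length(intersect(fail_wells, sample_wells)) /
    length(sample_wells)
  if (fail_frac > config$qc_max_fail)
    stop(errorCondition(
      sprintf("stage %d hpf: %.0f%% of sample wells fail hypoxia QC (floor %g mmHg)",
              hpf, 100 * fail_frac, config$qc_floor_mmHg),
      class = c("fluxdeconv_qc_abort", "fluxdeconv_error"),
      qc = qc))
  bad <- paste(qc$well, qc$cycle) [!qc$pass]
  rates$valid <- rates$valid & !(paste(rates$well, rates$cycle) %in% bad)

  rates <- apply_calibration(rates, factor)
  rates_s <- rates[rates$well %in% sample_wells, , drop = FALSE]
  phase <- extract_phase_rates(rates_s, schedule, n_cycles = sim$run$n_cycles)

  part <- partition(phase$ocr_basal, phase$ocr_oligomycin,
                    phase$ocr_azide, phase$ocr_fccp)
  n_emb <- sim$run$layout$n_embryos[match(phase$well, sim$run$layout$well)]
  part_pe <- per_embryo(part, n_emb)
  part_pe <- coxiv_normalize(part_pe, config$cox_index[[as.character(hpf)]])
  ppr_basal_pe <- ecar_to_ppr(phase$ecar_basal,
                              config$physics$bc_chamber) / n_emb

  data.frame(
    stage_hpf = hpf, well = phase$well, n_embryos = n_emb,
    ocr_basal = part$basal, ocr_oligo = part$oligo,
    ocr_azide = part$azide, ocr_fccp = part$fccp,
    ocr_basal_pe = part_pe$basal, ppr_basal_pe = as.numeric(ppr_basal_pe),
    mito_pe = part_pe$mito, atp_pe = part_pe$atp, leak_pe = part_pe$leak,
    nonmito_pe = part_pe$nonmito, maxunc_pe = part_pe$maxunc,
    f_nonmito = part$f_nonmito, f_atp = part$f_atp, f_leak = part$f_leak,
    mito_coxnorm_pe = part_pe$mito_coxnorm,
    maxunc_coxnorm_pe = part_pe$maxunc_coxnorm,
    negative_component = part$negative_component,
    qc_pass = !(phase$well %in% fail_wells),
    seed = stage_seed,
    stringsAsFactors = FALSE
  )
}

#' Linear development trend of a per-stage rate
#'
#' OLS of the per-embryo basal rate against developmental age.
#'
#' @param stage_means data frame with columns `hpf` and `rate` (>= 3
#'   stages).
#' @return List: `slope`, `intercept`, `r2`.
#' @export
fit_development_trend <- function(stage_means) {
  if (nrow(stage_means) < 3)
    abort("need at least 3 stages to fit a trend", "fluxdeconv_input_error")
  fit <- ols_slope(stage_means$hpf, stage_means$rate)
  intercept <- mean(stage_means$rate) - fit$slope * mean(stage_means$hpf)
  list(slope = fit$slope, intercept = intercept, r2 = fit$r2)
}

#' @export
print.flux_report <- function(x, ...) {
  cat("<flux_report>\n")
  cat(sprintf("  stages: %s | %d wells | calibration factor %.4g\n",
              paste(x$config$stages, collapse = ", "), nrow(x$wells),
              x$calibration_factor))
  s <- x$stage_summary
  show <- data.frame(
    hpf = s$stage_hpf, n = s$n_wells,
    OCR_pe = sprintf("%.1f +/- %.1f", s$ocr_basal_pe_mean, s$ocr_basal_pe_sem),
    PPR_pe = sprintf("%.2f +/- %.2f", s$ppr_basal_pe_mean, s$ppr_basal_pe_sem),
    leak_pct = sprintf("%.1f", 100 * s$f_leak_mean),
    nonmito_pct = sprintf("%.1f", 100 * s$f_nonmito_mean))
  print(show, row.names = FALSE)
  if (!is.null(x$trend))
    cat(sprintf("  basal OCR trend: %.2f pmol/min/embryo per hpf (R2 = %.3f)\n",
                x$trend$ocr$slope, x$trend$ocr$r2))
  invisible(x)
}

#' Write a report's tables to CSV
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$wells, file.path(dir, "wells.csv"), row.names = FALSE)
  write.csv(report$stage_summary, file.path(dir, "stage_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
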