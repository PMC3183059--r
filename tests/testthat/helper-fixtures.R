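## shared fixtures: all generated in code, nothing on disk

sample_wells_of <- function(run) {
  run$layout$well[run$layout$role == "sample"]
}

## run the trace -> rates -> extraction -> partition chain for one plate
partition_plate <- function(sim, method = "compartment",
                            physics = chamber_physics()) {
  rates <- estimate_ocr(sim$run, physics, method = method)
  sw <- sample_wells_of(sim$run)
  ph <- extract_phase_rates(rates[rates$well %in% sw, , drop = FALSE],
                            sim$run$schedule,
                            n_cycles = sim$run$n_cycles)
  cbind(ph["well"],
        partition(ph$ocr_basal, ph$ocr_oligomycin, ph$ocr_azide,
                  ph$ocr_fccp))
}

## a tiny hand-written two-well long-format trace (3 samples per well)
toy_trace_df <- function(wells = c("A2", "B1")) {
  do.call(rbind, lapply(wells, function(w)
    data.frame(well = w, time_min = c(3, 3.75, 4.5), cycle = 1L,
               phase = "measure",
               O2_mmHg = c(150, 149, 148), pH = c(7.4, 7.399, 7.398),
               stringsAsFactors = FALSE)))
}
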