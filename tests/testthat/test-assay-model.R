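test_that("stage lookup returns the tabulated assay parameters and refuses others", {
  s3 <- stage_config(3)
  expect_equal(s3$embryos_per_well, 3L)
  expect_equal(s3$stage, "Blastula")
  expect_equal(s3$fccp_uM, 1.875)

  s48 <- stage_config(48)
  expect_equal(s48$embryos_per_well, 1L)
  expect_equal(s48$azide_mM, 1.25)
  expect_equal(s48$fccp_uM, 2.5)

  ## FCCP switches concentration between 12 and 24 hpf; azide at 48 hpf
  expect_equal(stage_config(12)$fccp_uM, 1.875)
  expect_equal(stage_config(24)$fccp_uM, 2.5)
  expect_equal(stage_config(30)$azide_mM, 6.25)

  ## total on the six assayed stages, closed otherwise
  for (h in assayed_stages()) expect_s3_class(stage_config(h), "stage_config")
  expect_error(stage_config(5), class = "fluxdeconv_stage_error")
  expect_error(stage_config(36), class = "fluxdeconv_stage_error")
})

test_that("default islet layout is clean and issues name the offending wells", {
  layout <- plate_layout(24)
  expect_length(validate_layout(layout), 0)
  expect_setequal(layout$well[layout$role == "temperature_control"],
                  c("A1", "B3", "C4", "D6"))
  expect_true(all(layout$n_embryos[layout$role == "temperature_control"] == 0))

  bad <- layout
  bad$n_embryos[bad$well == "B3"] <- 2L
  issues <- validate_layout(bad)
  expect_length(issues, 1)
  expect_match(issues, "B3")

  three <- layout
  three$role[three$well == "D6"] <- "sample"
  three$n_embryos[three$well == "D6"] <- 2L
  expect_match(validate_layout(three), "expected 4 temperature control")

  empty <- layout
  empty$n_embryos[empty$well == "C2"] <- 0L
  expect_match(validate_layout(empty), "C2")
})

test_that("plate-run CSV IO round-trips losslessly and rejects bad files", {
  sim <- simulate_plate(12, schedule = NULL, seed = 7, n_cycles = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_run(sim$run, path)
  back <- load_plate_run(path, sim$run$layout)
  expect_equal(back$traces$O2_mmHg, sim$run$traces$O2_mmHg, tolerance = 1e-9)
  expect_equal(back$traces$pH, sim$run$traces$pH, tolerance = 1e-9)
  expect_identical(back$traces$well, sim$run$traces$well)
  expect_identical(back$traces$phase, sim$run$traces$phase)

  ## hand-written toy file
  toy <- toy_trace_df()
  toy_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy, toy_path, row.names = FALSE)
  run <- load_plate_run(toy_path, plate_layout(24))
  expect_length(unique(run$traces$well), 2)
  expect_equal(nrow(well_trace(run, "A2")), 3)

  ## rows outside the A-D x 1-6 grid are a layout error
  badwell <- toy
  badwell$well[1] <- "E1"
  write.csv(badwell, toy_path, row.names = FALSE)
  expect_error(load_plate_run(toy_path, plate_layout(24)),
               class = "fluxdeconv_layout_error")

  ## missing column is a format error naming the column
  nocol <- toy[, setdiff(names(toy), "pH")]
  write.csv(nocol, toy_path, row.names = FALSE)
  expect_error(load_plate_run(toy_path, plate_layout(24)), "pH",
               class = "fluxdeconv_format_error")

  ## non-monotone time is a data error
  backwards <- toy
  backwards$time_min[2] <- 5
  write.csv(backwards, toy_path, row.names = FALSE)
  expect_error(load_plate_run(toy_path, plate_layout(24)),
               class = "fluxdeconv_data_error")
})

test_that("well IDs are case-insensitive on read and emitted uppercase", {
  toy <- toy_trace_df()
  toy$well <- tolower(toy$well)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy, path, row.names = FALSE)
  run <- load_plate_run(path, plate_layout(24))
  expect_setequal(unique(run$traces$well), c("A2", "B1"))
})

test_that("injection schedules enforce the basal window and ordering", {
  expect_error(injection_schedule("oligomycin", 9.4, "uM", 5),
               class = "fluxdeconv_schedule_error")
  expect_error(injection_schedule(c("oligomycin", "fccp"), c(9.4, 2.5),
                                  c("uM", "uM"), c(13, 7)),
               class = "fluxdeconv_schedule_error")
  expect_error(injection_schedule("fccp", -1, "uM", 7),
               class = "fluxdeconv_schedule_error")
  sched <- default_schedule(30)
  expect_equal(sched$cycle, c(7L, 13L, 19L))
  expect_equal(sched$direction, c("min", "max", "min"))
  expect_equal(sched$concentration[2], 2.5)  # stage-titrated FCCP
  ## alternative agent labels map to the same response directions
  alt <- injection_schedule(c("oligomycin", "DNP", "rotenone"),
                            c(9.4, 100, 1), c("uM", "uM", "uM"),
                            c(7, 13, 19))
  expect_equal(alt$direction, c("min", "max", "min"))
})

test_that("clark traces validate geometry and IO round-trips", {
  tr <- simulate_clark_run(91, 2, 1.5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tr$samples, path, row.names = FALSE)
  back <- load_clark_trace(path, 1.5, 2)
  expect_equal(back$samples$O2_nmol_per_mL, tr$samples$O2_nmol_per_mL,
               tolerance = 1e-9)
  expect_error(clark_trace(tr$samples, volume_mL = 0, n_embryos = 1),
               class = "fluxdeconv_config_error")
})
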