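test_that("slope-method OCR is decline rate times chamber volume times solubility", {
  ## noiseless closed-chamber decline of 1 mmHg/min in a 7 uL chamber:
  ## 1 * 7 * 1.4 = 9.8 pmol/min
  t <- seq(3, 4.5, by = 0.15)
  tr <- data.frame(well = "A2", time_min = t, cycle = 1L, phase = "measure",
                   O2_mmHg = 155 - 1 * t, pH = 7.4)
  r <- estimate_ocr(tr, chamber_physics(), method = "slope")
  expect_equal(r$ocr_pmol_min, 9.8, tolerance = 1e-12)
  expect_equal(r$r2, 1)
})

test_that("compartment fit recovers generator truth on noiseless traces; slope under-reads", {
  sim <- simulate_plate(24, seed = 1, noise = FALSE)
  truth <- sim$truth$rates
  r_comp <- estimate_ocr(sim$run)
  r_slope <- estimate_ocr(sim$run, method = "slope")
  for (w in c("A2", "C1", "D5")) {
    tb <- truth$ocr_true[truth$well == w & truth$window == "basal"]
    comp <- r_comp$ocr_pmol_min[r_comp$well == w & r_comp$cycle <= 6]
    expect_equal(comp, rep(tb, 6), tolerance = 1e-9)
    slope <- r_slope$ocr_pmol_min[r_slope$well == w & r_slope$cycle <= 6]
    expect_true(all(slope < tb))       # diffusion/leak refill is ignored
    expect_true(all(slope > 0.8 * tb))
  }
  ## every injection window too, not just basal
  win <- c(oligomycin = 8L, fccp = 15L, azide = 21L)
  for (ag in names(win)) {
    tv <- truth$ocr_true[truth$well == "A2" & truth$window == ag]
    ev <- r_comp$ocr_pmol_min[r_comp$well == "A2" & r_comp$cycle == win[[ag]]]
    expect_equal(ev, tv, tolerance = 1e-9)
  }
})

test_that("estimated well OCR is proportional to embryo count (1-3 embryos, noiseless)", {
  for (h in c(3, 30)) {
    per_embryo_est <- vapply(1:3, function(n) {
      lay <- plate_layout(h, n_embryos = n)
      sim <- simulate_plate(h, layout = lay, seed = 1, noise = FALSE)
      r <- estimate_ocr(sim$run)
      r$ocr_pmol_min[r$well == "A2" & r$cycle == 5] / n
    }, 0)
    expect_equal(per_embryo_est[2] / per_embryo_est[1], 1, tolerance = 1e-6)
    expect_equal(per_embryo_est[3] / per_embryo_est[1], 1, tolerance = 1e-6)
  }
})

test_that("noiseless ECAR equals true PPR times chamber buffer capacity", {
  phys <- chamber_physics()
  sim <- simulate_plate(30, physics = phys, seed = 2, noise = FALSE)
  r <- estimate_ocr(sim$run)
  truth <- sim$truth$rates
  for (w in c("A2", "B4")) {
    ppr <- truth$ppr_true[truth$well == w & truth$window == "basal"]
    ecar <- r$ecar_mpH_min[r$well == w & r$cycle == 5]
    expect_equal(ecar, ppr * phys$bc_chamber, tolerance = 1e-9)
    ## and the conversion inverts it exactly
    expect_equal(as.numeric(ecar_to_ppr(ecar, phys$bc_chamber)), ppr,
                 tolerance = 1e-9)
  }
})

test_that("linearity R2 handles perfect, degenerate and noisy measure phases", {
  t <- seq(3, 4.5, by = 0.15)
  perfect <- data.frame(well = "A2", time_min = t, cycle = 1L,
                        phase = "measure", O2_mmHg = 150 - 2 * t, pH = 7.4)
  expect_equal(linearity_r2(perfect, 1), 1)

  flat <- perfect
  flat$O2_mmHg <- 150
  r2 <- linearity_r2(flat, 1)
  expect_equal(as.numeric(r2), 1)
  expect_true(attr(r2, "degenerate"))

  set.seed(9)
  noisy <- perfect
  noisy$O2_mmHg <- 150 - 0.5 * t + rnorm(length(t), 0, 5)
  expect_lt(linearity_r2(noisy, 1), 1)

  expect_error(linearity_r2(perfect[1:2, ], 1), class = "fluxdeconv_qc_error")
})

test_that("hypoxia QC fails any measure phase dipping below the floor", {
  t <- seq(3, 4.5, by = 0.15)
  tr <- rbind(
    data.frame(well = "A2", time_min = t, cycle = 1L, phase = "measure",
               O2_mmHg = seq(150, 120, length.out = length(t)), pH = 7.4),
    data.frame(well = "A2", time_min = t + 4.5, cycle = 2L, phase = "measure",
               O2_mmHg = seq(130, 95, length.out = length(t)), pH = 7.4))
  qc <- hypoxia_qc(tr)
  expect_equal(qc$pass, c(TRUE, FALSE))
  expect_true(all(hypoxia_qc(tr, floor_mmHg = 0)$pass))
})

test_that("cycles with too few measure samples are flagged invalid, not dropped", {
  t <- seq(3, 4.5, by = 0.15)
  tr <- rbind(
    data.frame(well = "A2", time_min = t, cycle = 1L, phase = "measure",
               O2_mmHg = 150 - t, pH = 7.4),
    data.frame(well = "A2", time_min = c(7.5, 7.65), cycle = 2L,
               phase = "measure", O2_mmHg = c(145, 144.8), pH = 7.4))
  r <- estimate_ocr(tr, method = "slope")
  expect_equal(nrow(r), 2)
  expect_equal(r$valid, c(TRUE, FALSE))
  expect_true(is.na(r$ocr_pmol_min[2]))
})

test_that("clark_ocr converts the closed-chamber slope and rejects O2 gain", {
  t <- seq(0, 30, by = 0.5)
  exact <- clark_trace(
    data.frame(time_min = t, O2_nmol_per_mL = 244 - 0.0607 * t), 1.5, 1)
  expect_equal(as.numeric(clark_ocr(exact)), 0.0607 * 1.5, tolerance = 1e-12)

  flat <- clark_trace(data.frame(time_min = t, O2_nmol_per_mL = 244), 1.5, 1)
  expect_equal(as.numeric(clark_ocr(flat)), 0)

  set.seed(3)
  gain <- clark_trace(
    data.frame(time_min = t,
               O2_nmol_per_mL = 244 + 0.1 * t + rnorm(length(t), 0, 0.05)),
    1.5, 1)
  expect_error(clark_ocr(gain), class = "fluxdeconv_data_error")
})
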