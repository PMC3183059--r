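test_that("default ground-truth table carries the published partition structure", {
  tab <- default_stage_table()
  expect_equal(tab[["24"]]$f_leak, 0.27)
  expect_equal(tab[["12"]]$f_leak, 0.27)
  expect_equal(tab[["30"]]$f_leak, 0.18)
  expect_equal(tab[["48"]]$f_leak, 0.094)
  expect_equal(tab[["3"]]$f_leak, 0)
  expect_equal(tab[["7"]]$f_leak, 0)
  ## Clark-anchored basal rate at 30 hpf, linear in age
  expect_equal(tab[["30"]]$ocr_per_embryo, 91)
  ocr <- vapply(tab, `[[`, 0, "ocr_per_embryo")
  hpf <- vapply(tab, `[[`, 0, "hpf")
  expect_equal(fit_development_trend(data.frame(hpf = hpf, rate = ocr))$r2, 1)
  ## generator identity: fractions partition the whole
  for (p in tab)
    expect_equal(p$f_nonmito + p$f_leak + p$f_atp, 1)
  ## overrides patch single fields
  tab2 <- default_stage_table(overrides = list(`24` = list(f_leak = 0.1)))
  expect_equal(tab2[["24"]]$f_leak, 0.1)
  expect_equal(tab2[["24"]]$f_nonmito, tab[["24"]]$f_nonmito)
})

test_that("stage parameter invariants are enforced", {
  expect_error(stage_params(24, 70, f_nonmito = 0.8, f_leak = 0.3,
                            fccp_fold = 1.5, ppr_per_embryo = 1),
               class = "fluxdeconv_config_error")
  expect_error(stage_params(24, -1, 0.3, 0.2, 1.5, 1),
               class = "fluxdeconv_config_error")
  expect_error(stage_params(24, 70, 0.3, 0.2, 1.5, 1, well_cv = -0.1),
               class = "fluxdeconv_config_error")
})

test_that("identical seeds give bit-identical plates; truth encodes the inhibitor responses", {
  a <- simulate_plate(24, seed = 11)
  b <- simulate_plate(24, seed = 11)
  expect_identical(a$run$traces, b$run$traces)
  expect_identical(a$truth, b$truth)
  c <- simulate_plate(24, seed = 12)
  expect_false(identical(a$run$traces$O2_mmHg, c$run$traces$O2_mmHg))

  ## forced by construction: azide leaves the non-mitochondrial fraction
  tr <- a$truth$rates
  smp <- tr[tr$well %in% sample_wells_of(a$run), ]
  basal <- smp$ocr_true[smp$window == "basal"]
  expect_equal(smp$ocr_true[smp$window == "azide"] / basal,
               rep(a$truth$params$f_nonmito, length(basal)))
  ## conservation: basal = nonmito + leak + atp at the truth level
  oligo <- smp$ocr_true[smp$window == "oligomycin"]
  azide <- smp$ocr_true[smp$window == "azide"]
  expect_equal(azide + (oligo - azide) + (basal - oligo), basal)
})

test_that("zero noise and zero diffusion/leak give exactly linear measure phases", {
  phys <- chamber_physics(k_w = 0, k_w2 = 0, k_a = 0)
  sim <- simulate_plate(30, physics = phys, seed = 1, noise = FALSE)
  tr <- well_trace(sim$run, "A2")
  for (cyc in c(1, 5, 10, 20))
    expect_equal(linearity_r2(tr, cyc), 1, tolerance = 1e-12)
})

test_that("the generator's trace matches an independent fine-step ODE integration", {
  skip_if_not_installed("deSolve")
  phys <- chamber_physics()
  sim <- simulate_plate(24, seed = 1, noise = FALSE)
  tr <- well_trace(sim$run, "A2")
  truth <- sim$truth$rates
  ocr_of_cycle <- function(cyc) {
    ag <- if (cyc < 7) "basal" else if (cyc < 13) "oligomycin" else
      if (cyc < 19) "fccp" else "azide"
    truth$ocr_true[truth$well == "A2" & truth$window == ag]
  }
  deriv <- function(t, y, parms) {
    closed <- parms$closed
    ocr <- parms$ocr
    dch <- -(if (closed) ocr / (phys$V_ch_uL * phys$k_O2) else 0) +
      phys$k_w * (y[2] - y[1]) + phys$k_a * (phys$O_atm - y[1]) +
      (if (closed) 0 else phys$k_mix * (phys$O_atm - y[1]))
    dw <- phys$k_w2 * (y[1] - y[2])
    list(c(dch, dw))
  }
  y <- c(phys$O_atm, phys$O_atm)
  got <- numeric(0)
  times_all <- numeric(0)
  for (cyc in 1:24) {
    t0 <- (cyc - 1) * 4.5
    sol_open <- deSolve::ode(y, seq(0, 3, by = 0.01), deriv,
                             list(closed = FALSE, ocr = 0),
                             rtol = 1e-10, atol = 1e-10)
    y <- unname(sol_open[nrow(sol_open), 2:3])
    sol_meas <- deSolve::ode(y, seq(0, 1.5, by = 0.01), deriv,
                             list(closed = TRUE, ocr = ocr_of_cycle(cyc)),
                             rtol = 1e-10, atol = 1e-10)
    y <- unname(sol_meas[nrow(sol_meas), 2:3])
    ## compare at the recorded measure-sample offsets
    m <- tr[tr$cycle == cyc & tr$phase == "measure", ]
    off <- round((m$time_min - t0 - 3) / 0.01)
    got <- c(got, sol_meas[off + 1, 2])
    times_all <- c(times_all, m$time_min)
  }
  want <- tr$O2_mmHg[tr$phase == "measure"]
  expect_equal(got, want, tolerance = 1e-7)
})

test_that("sample-well oxygen stays above the 100 mmHg floor at tabulated embryo counts", {
  for (h in assayed_stages()) {
    sim <- simulate_plate(h, seed = 3, noise = FALSE)
    qc <- hypoxia_qc(sim$run)
    expect_true(all(qc$pass), label = sprintf("stage %d hpf", h))
  }
})

test_that("clark simulation is linear in embryos and recoverable under noise", {
  noiseless <- simulate_clark_run(91, 1, 1.5, seed = 1, noise_sd = 0)
  ## 91 pmol/min in 1.5 mL: concentration falls 0.0607 nmol/mL/min
  o <- clark_ocr(noiseless)
  expect_equal(attr(o, "slope"), -91 / 1000 / 1.5, tolerance = 1e-12)
  expect_equal(as.numeric(o), 0.091, tolerance = 1e-12)

  two <- simulate_clark_run(91, 2, 1.5, seed = 1, noise_sd = 0)
  expect_equal(attr(clark_ocr(two), "slope"),
               2 * attr(clark_ocr(noiseless), "slope"), tolerance = 1e-12)

  noisy <- simulate_clark_run(91, 1, 1.5, seed = 42)
  est <- clark_ocr(noisy)
  se_ocr <- attr(est, "slope_se") * 1.5
  expect_lt(abs(as.numeric(est) - 0.091), 3 * se_ocr)
})

test_that("titration curves are Hill-monotone with zero response at zero dose", {
  cv <- simulate_titration("fccp", 7, c(0, 0.1, 0.2, 0.3, 0.4), seed = 1,
                           noise_cv = 0)
  expect_equal(cv$response[1], 0)
  expect_true(all(diff(cv$response) > 0))   # strictly increasing below EC50
  expect_false(any(cv$dead))
  expect_error(simulate_titration("fccp", 7, numeric(0)),
               class = "fluxdeconv_input_error")
})

test_that("FCCP titration at an early stage selects 1.875 uM as the working dose", {
  doses <- c(0.25, 0.5, 1, 1.875, 2.5, 5)
  cv <- simulate_titration("fccp", 7, doses, seed = 5, noise_cv = 0)
  expect_true(all(cv$dead[cv$dose > 2]))
  expect_equal(as.numeric(select_titration_dose(cv)), 1.875)
  ## and the late-stage config moves the selection to 2.5 uM
  cv24 <- simulate_titration("fccp", 24, doses, seed = 5, noise_cv = 0)
  expect_equal(as.numeric(select_titration_dose(cv24)), 2.5)
})

test_that("buffer titration follows the stated pH arithmetic", {
  tt <- simulate_buffer_titration(1, nmol_per_addition = 10, seed = 1,
                                  noise_sd_mpH = 0)
  expect_equal(nrow(tt), 6)            # baseline + 5 additions
  expect_equal(diff(tt$pH), rep(-0.01, 5))
  expect_error(simulate_buffer_titration(1, n_additions = 1),
               class = "fluxdeconv_input_error")
})
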