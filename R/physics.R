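## Two-compartment microchamber O2 model.
##
## When the sensor lowers (measure phase) the transient microchamber is
## closed: chamber O2 falls through organismal consumption, partly offset by
## back-diffusion from the plate wall and by atmospheric leak,
##
##   dO_ch/dt = -OCR/(V_ch k_O2) + k_w (O_w - O_ch) + k_a (O_atm - O_ch)
##   dO_w/dt  =  k_w2 (O_ch - O_w)
##
## while the wall compartment O_w slowly tracks the chamber.  With the sensor
## up (mix + wait) the chamber is open to the 700 uL bulk and re-equilibrates
## at the mixing rate k_mix.  The system is linear with piecewise-constant
## coefficients, so propagation over any interval is exact via the matrix
## exponential of the augmented 3x3 system; no step-size error anywhere.

#' Microchamber physics constants
#'
#' Defaults approximate an islet plate run in egg water at 28.5 C:
#' 7 uL effective microchamber, O2 solubility 1.4 pmol/(uL mmHg), ambient
#' tension 155 mmHg, slow wall diffusion and atmospheric leak, fast mixing
#' re-equilibration, and a chamber buffer capacity of 10 mpH per nmol H+.
#' Every value is overridable; none is instrument-certified.
#'
#' @param V_ch_uL microchamber volume, uL.
#' @param k_O2 O2 solubility, pmol per uL per mmHg.
#' @param k_w plate-wall diffusion rate into the chamber, 1/min.
#' @param k_w2 wall-compartment equilibration rate, 1/min.
#' @param k_a atmospheric leak rate, 1/min.
#' @param O_atm ambient (air-saturated) O2 tension, mmHg.
#' @param k_mix open-chamber re-equilibration rate, 1/min.
#' @param bc_chamber chamber buffer capacity, mpH per nmol H+.
#' @param pH0 bulk media pH.
#' @return A `chamber_physics` list.
#' @export
chamber_physics <- function(V_ch_uL = 7, k_O2 = 1.4, k_w = 0.06,
                            k_w2 = 0.06, k_a = 0.02, O_atm = 155,
                            k_mix = 3, bc_chamber = 10, pH0 = 7.4) {
  p <- list(V_ch_uL = V_ch_uL, k_O2 = k_O2, k_w = k_w, k_w2 = k_w2,
            k_a = k_a, O_atm = O_atm, k_mix = k_mix,
            bc_chamber = bc_chamber, pH0 = pH0)
  must_pos <- c("V_ch_uL", "k_O2", "O_atm", "k_mix", "bc_chamber", "pH0")
  for (nm in must_pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      abort(sprintf("physics constant %s must be positive", nm),
            "fluxdeconv_config_error")
  for (nm in c("k_w", "k_w2", "k_a"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      abort(sprintf("physics constant %s must be non-negative", nm),
            "fluxdeconv_config_error")
  class(p) <- "chamber_physics"
  p
}

#' @export
print.chamber_physics <- function(x, ...) {
  cat(sprintf(
    "<chamber_physics> V_ch %g uL, k_O2 %g pmol/uL/mmHg, k_w %g, k_a %g /min, O_atm %g mmHg\n",
    x$V_ch_uL, x$k_O2, x$k_w, x$k_a, x$O_atm))
  invisible(x)
}

## system matrix for a phase; state x = (O_ch, O_w)
phase_matrix <- function(physics, closed) {
  with(physics, {
    loss <- k_w + k_a + if (closed) 0 else k_mix
    matrix(c(-loss, k_w2, k_w, -k_w2), nrow = 2)
  })
}

## constant forcing for a phase at a given OCR (pmol/min)
phase_forcing <- function(physics, closed, ocr = 0) {
  with(physics, {
    src <- k_a * O_atm + if (closed) 0 else k_mix * O_atm
    c(src - if (closed) ocr / (V_ch_uL * k_O2) else 0, 0)
  })
}

## exact one-step propagator for x' = M x + b over dt:
## x(t+dt) = Phi x(t) + psi, from the augmented matrix exponential
lin2_step <- function(M, b, dt) {
  E <- as.matrix(Matrix::expm(rbind(cbind(M, b), 0) * dt))
  list(Phi = E[1:2, 1:2, drop = FALSE], psi = E[1:2, 3])
}

## stepper with memoised (phase, dt) -> {Phi, psi0, psi_unit} pieces.
## Forcing is affine in OCR, so psi(ocr) = psi0 + ocr * psi_unit and the
## chamber response is linear in OCR (superposition) -- the basis of the
## closed-form compartment fit in estimate_ocr().
make_stepper <- function(physics) {
  cache <- new.env(parent = emptyenv())
  get_pieces <- function(closed, dt) {
    key <- sprintf("%d_%.12g", as.integer(closed), dt)
    if (!is.null(cache[[key]])) return(cache[[key]])
    M <- phase_matrix(physics, closed)
    s0 <- lin2_step(M, phase_forcing(physics, closed, 0), dt)
    pieces <- list(Phi = s0$Phi, psi0 = s0$psi)
    if (closed) {
      su <- lin2_step(M, c(-1 / (physics$V_ch_uL * physics$k_O2), 0), dt)
      pieces$psi_unit <- su$psi
    }
    cache[[key]] <- pieces
    pieces
  }
  list(
    ## advance state over dt at consumption `ocr` (closed) or open chamber
    advance = function(x, dt, closed, ocr = 0) {
      if (dt <= 0) return(x)
      p <- get_pieces(closed, dt)
      psi <- p$psi0
      if (closed && ocr != 0) psi <- psi + ocr * p$psi_unit
      drop(p$Phi %*% x) + psi
    },
    pieces = get_pieces,
    physics = physics
  )
}
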