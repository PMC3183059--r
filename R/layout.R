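## 24-well islet-plate geometry: rows A-D x columns 1-6, row-major.
## Four specimen-free temperature-control wells; all other wells hold embryos.

PLATE_ROWS <- c("A", "B", "C", "D")
PLATE_COLS <- 1:6

#' All well identifiers of a 24-well plate, row-major
#'
#' @return Character vector of 24 well IDs ("A1" ... "D6").
#' @export
plate_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Default temperature-control wells
#'
#' The islet-plate protocol reserves four specimen-free wells, spread across
#' the plate, for thermal/background correction: A1, B3, C4 and D6.
#'
#' @return Character vector of four well IDs.
#' @export
control_wells <- function() c("A1", "B3", "C4", "D6")

normalize_well <- function(well) toupper(trimws(as.character(well)))

is_valid_well <- function(well) normalize_well(well) %in% plate_wells()

#' Construct a plate layout
#'
#' A plate layout assigns each of the 24 wells a role (`"sample"` or
#' `"temperature_control"`), an embryo count and a developmental stage.
#' Control wells always carry zero embryos.
#'
#' @param stage_hpf developmental stage, hours post-fertilization, applied to
#'   every sample well.
#' @param n_embryos embryos per sample well; defaults to the stage's
#'   tabulated count (see [stage_config()]).
#' @param controls well IDs of the temperature-control wells.
#' @param plate_type `"islet"` (default) or `"V28"`.
#' @return A `plate_layout`: data frame with columns `well`, `role`,
#'   `n_embryos`, `stage_hpf`, plus a `plate_type` attribute.
#' @export
plate_layout <- function(stage_hpf, n_embryos = NULL,
                         controls = control_wells(),
                         plate_type = c("islet", "V28")) {
  plate_type <- match.arg(plate_type)
  controls <- normalize_well(controls)
  bad <- setdiff(controls, plate_wells())
  if (length(bad) > 0)
    abort(paste0("unknown control well(s): ", paste(bad, collapse = ", ")),
          "fluxdeconv_layout_error")
  if (is.null(n_embryos)) n_embryos <- stage_config(stage_hpf)$embryos_per_well
  wells <- plate_wells()
  role <- ifelse(wells %in% controls, "temperature_control", "sample")
  layout <- data.frame(
    well = wells,
    role = role,
    n_embryos = ifelse(role == "sample", n_embryos, 0L),
    stage_hpf = stage_hpf,
    stringsAsFactors = FALSE
  )
  attr(layout, "plate_type") <- plate_type
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Validate a plate layout
#'
#' Checks the structural expectations of the islet-plate protocol and returns
#' human-readable issues rather than raising: exactly 24 unique wells within
#' the A-D x 1-6 grid, exactly four temperature-control wells, control wells
#' embryo-free, and every sample well holding at least one embryo.
#'
#' @param layout a `plate_layout` (or plain data frame with the same columns).
#' @return Character vector of issues; empty when the layout is clean.
#' @export
validate_layout <- function(layout) {
  issues <- character(0)
  need <- c("well", "role", "n_embryos")
  miss <- setdiff(need, names(layout))
  if (length(miss) > 0)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  wells <- normalize_well(layout$well)
  if (anyDuplicated(wells))
    issues <- c(issues, "duplicated well IDs")
  unknown <- setdiff(wells, plate_wells())
  if (length(unknown) > 0)
    issues <- c(issues, paste0("unknown well ID(s): ",
                               paste(unknown, collapse = ", ")))
  if (nrow(layout) != 24)
    issues <- c(issues, sprintf("expected 24 wells, found %d", nrow(layout)))
  ctrl <- layout[layout$role == "temperature_control", , drop = FALSE]
  if (nrow(ctrl) != 4)
    issues <- c(issues,
                sprintf("expected 4 temperature control wells, found %d",
                        nrow(ctrl)))
  bad_ctrl <- ctrl$well[ctrl$n_embryos != 0]
  if (length(bad_ctrl) > 0)
    issues <- c(issues,
                paste0("temperature control well(s) with embryos: ",
                       paste(normalize_well(bad_ctrl), collapse = ", ")))
  smp <- layout[layout$role == "sample", , drop = FALSE]
  empty <- smp$well[smp$n_embryos < 1]
  if (length(empty) > 0)
    issues <- c(issues, paste0("sample well(s) without embryos: ",
                               paste(normalize_well(empty), collapse = ", ")))
  issues
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s plate, %d sample wells, %d control wells\n",
              attr(x, "plate_type") %||% "islet",
              sum(x$role == "sample"), sum(x$role == "temperature_control")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
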