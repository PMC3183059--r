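## Developmental-stage lookup for the six assayed timepoints.  The assay was
## only characterised at these stages, so the lookup is closed: no
## interpolation to other ages.

STAGE_TABLE <- data.frame(
  hpf = c(3L, 7L, 12L, 24L, 30L, 48L),
  stage = c("Blastula", "Gastrula", "Segmentation",
            "Segmentation/Pharyngula Transition", "Mid-Pharyngula",
            "Hatching"),
  embryos_per_well = c(3L, 2L, 2L, 2L, 2L, 1L),
  fccp_uM = c(1.875, 1.875, 1.875, 2.5, 2.5, 2.5),
  azide_mM = c(6.25, 6.25, 6.25, 6.25, 6.25, 1.25),
  oligomycin_uM = rep(9.4, 6),
  stringsAsFactors = FALSE
)

#' Assayed developmental stages
#'
#' @return Integer vector of the six assayed timepoints (hours
#'   post-fertilization).
#' @export
assayed_stages <- function() STAGE_TABLE$hpf

#' Stage configuration lookup
#'
#' Returns the per-stage assay parameters: stage name, embryos plated per
#' well (3 at 3 hpf down to 1 at 48 hpf, chosen so oxygen tension stays in
#' the instrument's working range), and the titrated inhibitor
#' concentrations (1.875 uM FCCP for 3-12 hpf vs 2.5 uM for 24-48 hpf;
#' 6.25 mM sodium azide for 3-30 hpf vs 1.25 mM for 48 hpf; 9.4 uM
#' oligomycin throughout).
#'
#' @param hpf one of 3, 7, 12, 24, 30, 48 (hours post-fertilization).
#' @return A `stage_config` list: `hpf`, `stage`, `embryos_per_well`,
#'   `fccp_uM`, `azide_mM`, `oligomycin_uM`.
#' @export
stage_config <- function(hpf) {
  i <- match(hpf, STAGE_TABLE$hpf)
  if (length(hpf) != 1 || is.na(i))
    abort(sprintf(
      "unknown stage %s hpf: assayed stages are %s (no interpolation)",
      paste(hpf, collapse = ","),
      paste(STAGE_TABLE$hpf, collapse = ", ")),
      "fluxdeconv_stage_error")
  cfg <- as.list(STAGE_TABLE[i, ])
  class(cfg) <- "stage_config"
  cfg
}

#' @export
print.stage_config <- function(x, ...) {
  cat(sprintf(
    "<stage_config> %d hpf (%s): %d embryo(s)/well, FCCP %g uM, azide %g mM\n",
    x$hpf, x$stage, x$embryos_per_well, x$fccp_uM, x$azide_mM))
  invisible(x)
}

#' Mitochondrial-content index (COX IV / beta-actin), synthetic defaults
#'
#' A per-stage index of mitochondrial content: COX IV densitometry
#' normalized to a beta-actin loading control, rescaled so the 3 hpf value
#' is 1.  The values shipped here are synthetic defaults with the expected
#' qualitative shape (monotone increase with development, steepest late);
#' real densitometry should be supplied by the user when available.
#'
#' @param hpf optional stage filter; default all six stages.
#' @return Named numeric vector, names = hpf, values = index (3 hpf == 1).
#' @export
cox_iv_index <- function(hpf = assayed_stages()) {
  idx <- c(`3` = 1, `7` = 1.5, `12` = 2.2, `24` = 3.4, `30` = 4.6, `48` = 7)
  key <- as.character(hpf)
  if (any(!key %in% names(idx)))
    abort("COX IV index only tabulated for the six assayed stages",
          "fluxdeconv_stage_error")
  idx[key]
}
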