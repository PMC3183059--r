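## Injection schedule: up to four sensor-cartridge ports, each delivering one
## agent at a given measurement cycle.  Six basal cycles always precede the
## first injection.

N_BASAL_CYCLES <- 6L

## canonical direction of the respiration response for each agent class
AGENT_DIRECTION <- c(
  oligomycin = "min",
  fccp = "max", dnp = "max",
  azide = "min", rotenone = "min", antimycin = "min"
)

agent_key <- function(agent) {
  key <- tolower(trimws(agent))
  key[key %in% c("sodium azide", "sodium_azide", "nan3")] <- "azide"
  key[key %in% c("antimycin a", "antimycin_a")] <- "antimycin"
  key[key %in% c("2,4-dinitrophenol", "dinitrophenol")] <- "dnp"
  key
}

#' Construct an injection schedule
#'
#' @param agents character vector (<= 4) of agent labels; recognised classes
#'   are oligomycin, FCCP/DNP (uncouplers) and azide/rotenone/antimycin
#'   (respiratory-chain inhibitors).
#' @param concentrations positive numeric, final concentration per agent.
#' @param units character, units per agent (e.g. `"uM"`, `"mM"`).
#' @param cycles integer, measurement cycle at which each port fires;
#'   strictly increasing and > 6 (the basal cycles).
#' @return An `injection_schedule` data frame with columns `port`, `agent`,
#'   `concentration`, `units`, `cycle`, `direction`.
#' @export
injection_schedule <- function(agents, concentrations, units, cycles) {
  n <- length(agents)
  if (n < 1 || n > 4)
    abort("an injection schedule has 1-4 ports", "fluxdeconv_schedule_error")
  if (length(concentrations) != n || length(units) != n ||
      length(cycles) != n)
    abort("agents, concentrations, units and cycles must have equal length",
          "fluxdeconv_schedule_error")
  if (any(concentrations <= 0))
    abort("injection concentrations must be positive",
          "fluxdeconv_schedule_error")
  cycles <- as.integer(cycles)
  if (any(cycles <= N_BASAL_CYCLES))
    abort(sprintf("injection cycles must follow the %d basal cycles",
                  N_BASAL_CYCLES), "fluxdeconv_schedule_error")
  if (any(diff(cycles) <= 0))
    abort("injection cycles must be strictly increasing",
          "fluxdeconv_schedule_error")
  key <- agent_key(agents)
  unknown <- setdiff(key, names(AGENT_DIRECTION))
  if (length(unknown) > 0)
    abort(paste0("unrecognised agent(s): ", paste(unknown, collapse = ", ")),
          "fluxdeconv_schedule_error")
  sched <- data.frame(
    port = seq_len(n),
    agent = key,
    concentration = concentrations,
    units = units,
    cycle = cycles,
    direction = unname(AGENT_DIRECTION[key]),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("injection_schedule", "data.frame")
  sched
}

#' Default mitochondrial stress-test schedule for a stage
#'
#' Oligomycin at cycle 7, uncoupler (FCCP) at cycle 13, sodium azide at
#' cycle 19, using the stage's titrated concentrations; six basal cycles
#' precede the first injection and each agent gets six measurement cycles.
#'
#' @param stage_hpf one of the assayed stages.
#' @param n_cycles total cycles in the run (default 24 = 6 basal + 18).
#' @return An [injection_schedule()].
#' @export
default_schedule <- function(stage_hpf, n_cycles = 24L) {
  cfg <- stage_config(stage_hpf)
  injection_schedule(
    agents = c("oligomycin", "fccp", "azide"),
    concentrations = c(cfg$oligomycin_uM, cfg$fccp_uM, cfg$azide_mM),
    units = c("uM", "uM", "mM"),
    cycles = c(7L, 13L, 19L)
  )
}

## cycle windows per injection: from its firing cycle to the cycle before the
## next injection (or the last cycle of the run)
schedule_windows <- function(schedule, n_cycles) {
  ends <- c(schedule$cycle[-1] - 1L, n_cycles)
  data.frame(agent = schedule$agent,
             direction = schedule$direction,
             from = schedule$cycle, to = ends,
             stringsAsFactors = FALSE)
}

## agent in force at a given cycle; NA while basal
agent_at_cycle <- function(schedule, cycle) {
  fired <- schedule$cycle <= cycle
  if (!any(fired)) return(NA_character_)
  schedule$agent[max(which(fired))]
}
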