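# flat config dialect: every key is a field name of the scenario
CONFIG_RATE_KEYS <- c(
  "k_M_prolif", "k_M_apop", "k_N_prolif", "k_N_apop", "k_diff", "k_senesc",
  "k_relapse", "k_wake", "k_E_prolif", "k_E_apop", "k_D_apop",
  "k_inactivation", "k_activation", "tau_apop", "dt"
)
CONFIG_KEYS <- c(
  "preset", "name", "tumor_type", "immune_status", CONFIG_RATE_KEYS,
  STATES, "initial_program", "switch_times", "switch_programs",
  "t_end", "n_replicates", "bli_states"
)

#' Load a scenario from a config file
#'
#' Reads a flat YAML key-value file into a fully validated
#' [scenario_preset()]-style scenario.  Recognized keys: `preset` (a named
#' preset used as the base), `name`, `tumor_type`, `immune_status`, every
#' rate field of [onco_params()] (including `tau_apop` and `dt`), initial
#' counts under the state letters `M`,`N`,`A`,`D`,`S`,`E`, the schedule
#' fields `initial_program`/`switch_times`/`switch_programs`, and `t_end`,
#' `n_replicates`, `bli_states`.  Unknown keys are rejected by name (typo
#' guard), and all parameter invariants are re-validated, so a config whose
#' `dt` makes some per-step probability exceed 1 fails with a step-size
#' error.
#'
#' @param path Path to a YAML config file.
#' @return An `onco_scenario`.
#' @seealso [write_config()] for the exact inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Config must be a YAML mapping.")
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad)) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }

  if (!is.null(cfg$preset)) {
    base <- scenario_preset(cfg$preset)
  } else {
    base <- structure(
      list(
        name = cfg$name %||% "custom",
        description = "user configuration",
        params = onco_params(
          cfg$tumor_type %||% "lymphoma",
          cfg$immune_status %||% "competent"
        ),
        initial = cell_state(M = 1e6),
        schedule = myc_schedule("on", switch_times = 10),
        t_end = 40,
        n_replicates = 1,
        bli_states = STATES
      ),
      class = "onco_scenario"
    )
  }

  if (!is.null(cfg$preset) && (!is.null(cfg$tumor_type) || !is.null(cfg$immune_status))) {
    base$params <- onco_params(
      cfg$tumor_type %||% attr(base$params, "tumor_type"),
      cfg$immune_status %||% attr(base$params, "immune_status"),
      tau_apop = base$params$tau_apop, dt = base$params$dt
    )
  }

  rates <- cfg[intersect(names(cfg), CONFIG_RATE_KEYS)]
  if (length(rates)) {
    base$params[names(rates)] <- lapply(rates, as.numeric)
    base$params <- validate_onco_params(base$params)
  }

  counts <- cfg[intersect(names(cfg), STATES)]
  if (length(counts)) {
    init <- as.list(base$initial)
    init[names(counts)] <- lapply(counts, as.numeric)
    base$initial <- do.call(cell_state, init)
  }

  if (!is.null(cfg$initial_program) || !is.null(cfg$switch_times)) {
    base$schedule <- myc_schedule(
      initial_program = cfg$initial_program %||% base$schedule$initial_program,
      switch_times = cfg$switch_times %||% base$schedule$switch_times,
      switch_programs = cfg$switch_programs
    )
  }

  if (!is.null(cfg$t_end)) base$t_end <- as.numeric(cfg$t_end)
  if (!is.null(cfg$n_replicates)) base$n_replicates <- as.integer(cfg$n_replicates)
  if (!is.null(cfg$bli_states)) {
    base$bli_states <- match.arg(cfg$bli_states, STATES, several.ok = TRUE)
  }
  if (!is.null(cfg$name)) base$name <- cfg$name
  base
}

#' Write a scenario to a config file
#'
#' Serializes an `onco_scenario` to the flat YAML dialect read by
#' [load_config()]; `load_config(write_config(x, path))` reproduces `x`
#' exactly.
#'
#' @param scenario An `onco_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "onco_scenario"))
  cfg <- c(
    list(
      name = scenario$name,
      tumor_type = attr(scenario$params, "tumor_type"),
      immune_status = attr(scenario$params, "immune_status")
    ),
    unclass(scenario$params)[CONFIG_RATE_KEYS],
    as.list(scenario$initial),
    list(
      initial_program = scenario$schedule$initial_program,
      switch_times = scenario$schedule$switch_times,
      switch_programs = scenario$schedule$switch_programs,
      t_end = scenario$t_end,
      n_replicates = scenario$n_replicates,
      bli_states = scenario$bli_states
    )
  )
  # drop empty schedule vectors so the YAML stays minimal
  cfg <- cfg[vapply(cfg, length, 1L) > 0]
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
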