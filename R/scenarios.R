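# Scenario presets: age group x glucose concentration (and GKA variants).
#
# The presets are calibrations, not measured constants: recruitment and death
# hazards were chosen so that the simulated orderings and signs (which age
# and glucose conditions grow, shrink or stay flat; which carry high dead
# fractions; which show dual-label re-entry suppression) come out right,
# while cycle length, S-phase fraction and refractory duration are free
# model parameters. See the package vignette for the calibration rationale.

#' Names of the shipped scenario presets
#'
#' @return Character vector of preset names accepted by
#'   [scenario_config()] and [reproduce()].
#' @export
scenario_names <- function() {
  files <- list.files(system.file("extdata", "scenarios", package = "betakin"),
                      pattern = "\\.cfg$")
  sub("\\.cfg$", "", files)
}

#' Load a shipped scenario preset
#'
#' @param name Preset name, e.g. `"adult_10mM"`; see [scenario_names()].
#' @param ... Overrides (any [sim_config()] argument), e.g.
#'   `n_cells_initial` or `rng_seed`.
#' @return A [sim_config()].
#' @export
scenario_config <- function(name, ...) {
  path <- system.file("extdata", "scenarios", paste0(name, ".cfg"),
                      package = "betakin")
  if (!nzchar(path) || !file.exists(path)) {
    stop_config("unknown scenario '", name, "'; available: ",
                paste(scenario_names(), collapse = ", "))
  }
  read_sim_config(path, ...)
}
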