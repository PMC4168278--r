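# Published reference impedances for cortical-stimulation volume-conductor
# models (slab and realistic geometries, by conductivity model and electrode
# configuration), shipped as plain text. Used as Ohm's-law worked examples:
# given the impedance, the package's voltage/current conversion reproduces
# the reported output current at 1 V.

#' Reference impedance table
#'
#' Reported impedances (ohm) and output currents (mA) at 1 V for a set of
#' cortical-stimulation volume-conductor models: a simplified extruded slab
#' and realistic upper-body/brain-only geometries, each under isotropic or
#' anisotropic white matter and paddle-array or single-electrode
#' configurations. One slab row is flagged `self_consistent = FALSE`: its
#' printed impedance and current do not satisfy V = I Z (apparently a
#' typographical error in the source table) and it is excluded from
#' worked-example checks.
#'
#' @return data.frame with columns model, conductivity_model,
#'   electrode_config, impedance_ohm, reported_output_current_mA,
#'   self_consistent.
#' @export
reference_impedances <- function() {
  utils::read.csv(system.file("extdata", "reported_impedances.csv",
                              package = "sucsim", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Ohm's-law worked examples from the reference table
#'
#' For every self-consistent reference row, converts the applied voltage to
#' an output current through the model impedance
#' (`I = 1000 * V / Z` mA) — the same conversion the simulator uses to map
#' voltage-controlled to current-controlled stimulation.
#'
#' @param V0 applied voltage, volts (default 1, matching the reported
#'   currents).
#' @return the reference table with a `computed_output_current_mA` column,
#'   self-consistent rows only.
#' @export
ohms_law_examples <- function(V0 = 1) {
  tab <- reference_impedances()
  tab <- tab[tab$self_consistent, ]
  tab$computed_output_current_mA <- 1000 * V0 / tab$impedance_ohm
  tab
}
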