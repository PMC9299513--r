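#' Single-cell specification
#'
#' One whole-cell recording target: a set of channel models, an ohmic leak,
#' the cell capacitance (metadata under ideal voltage clamp), the additive
#' recording noise level, and the RNG seed that makes the cell's simulated
#' recordings reproducible.
#'
#' @param channels List of [channel_model()] objects (possibly empty for a
#'   leak-only cell).
#' @param capacitance_pF Membrane capacitance, pF (> 0). Default 27 pF, the
#'   mean capacitance of the recorded cells.
#' @param leak_conductance_nS Ohmic leak conductance, nS (>= 0).
#' @param leak_erev_mV Leak reversal potential, mV.
#' @param noise_sd_pA Standard deviation of the additive i.i.d. Gaussian
#'   recording noise per sample, pA. Default 3 pA.
#' @param seed Integer seed for the cell's noise stream.
#' @param cell_id Identifier used in sweep sets and reports.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(channels = list(), capacitance_pF = 27,
                      leak_conductance_nS = 0.5, leak_erev_mV = -20,
                      noise_sd_pA = 3, seed = 1L, cell_id = "cell") {
  if (!is.list(channels) ||
      !all(vapply(channels, inherits, TRUE, "channel_model")))
    stop("`channels` must be a list of channel_model objects")
  if (!is.finite(capacitance_pF) || capacitance_pF <= 0)
    stop("`capacitance_pF` must be positive")
  if (!is.finite(leak_conductance_nS) || leak_conductance_nS < 0)
    stop("`leak_conductance_nS` must be non-negative")
  if (!is.finite(noise_sd_pA) || noise_sd_pA < 0)
    stop("`noise_sd_pA` must be non-negative")
  structure(
    list(channels = channels, capacitance_pF = capacitance_pF,
         leak_conductance_nS = leak_conductance_nS,
         leak_erev_mV = leak_erev_mV, noise_sd_pA = noise_sd_pA,
         seed = as.integer(seed), cell_id = as.character(cell_id)),
    class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  fams <- vapply(x$channels, `[[`, "", "family")
  cat(sprintf(
    "<cell_spec> %s: %d channel(s) [%s], C %g pF, leak %g nS -> %g mV, noise %g pA\n",
    x$cell_id, length(fams), paste(fams, collapse = ", "),
    x$capacitance_pF, x$leak_conductance_nS, x$leak_erev_mV, x$noise_sd_pA))
  invisible(x)
}

#' Apply a pharmacological or ion-substitution modifier to a cell
#'
#' Scales every channel's maximal conductance by that channel's fractional
#' sensitivity to the modifier (default 1, i.e. unaffected). Modifier names
#' shipped with the presets: `"ba2"` (5 mM Ba2+), `"tea"` (20 mM TEA),
#' `"agitoxin2"` (10 nM Agitoxin-2), `"linopirdine"` (300 nM linopirdine) and
#' `"rb"` (Rb+-for-Na+ bath substitution). The `"rb"` modifier only rescales
#' conductances here; [simulate_sweeps()] additionally swaps the Na+ bath for
#' the Rb+ bath so that reversal potentials (and the LJP) are recomputed.
#'
#' @param cell A [cell_spec()].
#' @param modifier Modifier name.
#' @param strict If `TRUE`, error when no channel in the cell defines a
#'   sensitivity for `modifier`.
#' @return A [cell_spec()] with scaled conductances.
#' @export
apply_modifier <- function(cell, modifier, strict = FALSE) {
  stopifnot(inherits(cell, "cell_spec"), is.character(modifier),
            length(modifier) == 1L)
  known <- vapply(cell$channels, function(ch)
    modifier %in% names(ch$modifier_sensitivity), TRUE)
  if (strict && !any(known))
    stop(sprintf("unknown modifier '%s' for this cell", modifier))
  cell$channels <- lapply(cell$channels, function(ch) {
    mult <- ch$modifier_sensitivity[[modifier]]
    if (!is.null(mult)) ch$gmax_nS <- ch$gmax_nS * mult
    ch
  })
  cell
}
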