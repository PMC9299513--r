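# Physical constants (SI)
.FARADAY <- 96485.33212   # C / mol
.GAS_R <- 8.31446262      # J / (mol K)

#' Ionic solution
#'
#' Represents one pipette or bath solution by its ionic concentrations, its
#' temperature and the liquid junction potential (LJP) it develops against the
#' standard KCl/K-gluconate pipette solution.
#'
#' @param name Short identifier, e.g. `"ames"`.
#' @param concentrations_mM Named numeric vector (or list) of free ion
#'   concentrations in millimolar. Must contain `K` with a positive value;
#'   `Na`, `Rb`, `Cl`, ... are optional.
#' @param temperature_K Absolute temperature in kelvin. Default 295 K
#'   (room temperature).
#' @param ljp_mV Measured liquid junction potential of this solution against
#'   the standard pipette solution, in millivolt. 0 where the LJP is
#'   negligible.
#'
#' @return An object of class `ionic_solution`.
#' @seealso [bath_preset()], [pipette_preset()], [nernst_potential()]
#' @export
ionic_solution <- function(name, concentrations_mM, temperature_K = 295,
                           ljp_mV = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  conc <- unlist(concentrations_mM)
  if (is.null(names(conc)) || any(!nzchar(names(conc))))
    stop("`concentrations_mM` must be named by ion symbol")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("ion concentrations must be finite and non-negative")
  if (!("K" %in% names(conc)) || conc[["K"]] <= 0)
    stop("solution must contain K at a positive concentration")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("`temperature_K` must be a positive temperature in kelvin")
  if (!is.finite(ljp_mV))
    stop("`ljp_mV` must be finite")
  structure(
    list(name = name, concentrations_mM = conc,
         temperature_K = temperature_K, ljp_mV = ljp_mV),
    class = "ionic_solution")
}

#' @export
print.ionic_solution <- function(x, ...) {
  cat(sprintf("<ionic_solution> %s (%.0f K, LJP %g mV)\n",
              x$name, x$temperature_K, x$ljp_mV))
  print(x$concentrations_mM)
  invisible(x)
}

.solution_conc <- function(sol, ion) {
  conc <- sol$concentrations_mM
  if (ion %in% names(conc)) unname(conc[[ion]]) else 0
}

#' Bath solution presets
#'
#' The three extracellular solutions used for RPE whole-cell recordings.
#'
#' * `"ames"` -- Ames' medium with 10 mM HEPES and 10 mM extra NaCl; its LJP
#'   against the pipette solution is negligible (0 mV). The free K+
#'   concentration of Ames' medium is not printed on the formulation used and
#'   ships here as a documented default of 3.6 mM (assumption, overridable by
#'   constructing the solution directly).
#' * `"na_based"` -- 120 NaCl, 3 KCl, 1.1 CaCl2, 1.2 MgCl2 bath; measured
#'   LJP 11 mV.
#' * `"rb_based"` -- the Na+-based solution with NaCl replaced by an
#'   equivalent amount of RbCl (120 RbCl, 3 KCl); measured LJP 4 mV.
#'
#' @param name One of `"ames"`, `"na_based"`, `"rb_based"`.
#' @param temperature_K Temperature in kelvin.
#' @return An [ionic_solution()].
#' @export
bath_preset <- function(name = c("ames", "na_based", "rb_based"),
                        temperature_K = 295) {
  name <- match.arg(name)
  switch(name,
    ames = ionic_solution("ames",
      c(K = 3.6, Na = 154, Cl = 130, Ca = 1.15, Mg = 1.2),
      temperature_K = temperature_K, ljp_mV = 0),
    na_based = ionic_solution("na_based",
      c(K = 3, Na = 120, Cl = 127.6, Ca = 1.1, Mg = 1.2),
      temperature_K = temperature_K, ljp_mV = 11),
    rb_based = ionic_solution("rb_based",
      c(K = 3, Rb = 120, Na = 0, Cl = 127.6, Ca = 1.1, Mg = 1.2),
      temperature_K = temperature_K, ljp_mV = 4))
}

#' Standard pipette (internal) solution
#'
#' KCl/K-gluconate internal solution: 25 KCl + 83 K-gluconate gives a total
#' pipette K+ of 108 mM (KOH used for pH titration is ignored, as a documented
#' assumption); 5 NaCl + 0.1 GTP-Na gives ~5.1 mM Na+.
#'
#' @param temperature_K Temperature in kelvin.
#' @return An [ionic_solution()].
#' @export
pipette_preset <- function(temperature_K = 295) {
  ionic_solution("kcl_gluconate_pipette",
    c(K = 108, Na = 5.1, Cl = 33, Ca = 0.5, Mg = 4),
    temperature_K = temperature_K, ljp_mV = 0)
}

#' Nernst equilibrium potential
#'
#' \eqn{E = (RT/zF)\,\ln([X]_{out}/[X]_{in})}, returned in millivolt. The
#' temperature of the outside (bath) solution is used.
#'
#' @param inside,outside [ionic_solution()] objects on the two membrane faces.
#' @param ion Ion symbol, default `"K"`.
#' @param z Ion valence (monovalent cation assumed by default).
#' @return Equilibrium potential in mV.
#' @examples
#' pip <- pipette_preset()
#' nernst_potential(pip, bath_preset("na_based"))  # about -91 mV
#' @export
nernst_potential <- function(inside, outside, ion = "K", z = 1) {
  stopifnot(inherits(inside, "ionic_solution"),
            inherits(outside, "ionic_solution"))
  cin <- .solution_conc(inside, ion)
  cout <- .solution_conc(outside, ion)
  if (cin <= 0 || cout <= 0)
    stop(sprintf("ion '%s' must have a positive concentration on both sides",
                 ion))
  t_k <- outside$temperature_K
  1000 * (.GAS_R * t_k) / (z * .FARADAY) * log(cout / cin)
}

#' Potassium-channel reversal potential with Rb+ as a K-like permeant
#'
#' For K+ channels in Rb+-substituted baths the reversal potential is computed
#' with Rb+ folded into the K+ gradient at a configurable permeability ratio
#' (default 1, i.e. Rb+ treated as fully K-like):
#' \eqn{E = (RT/F)\ln\big(([K]_o + p[Rb]_o)/([K]_i + p[Rb]_i)\big)}.
#'
#' @param pipette,bath [ionic_solution()] objects.
#' @param rb_permeability Permeability of Rb+ relative to K+.
#' @return Reversal potential in mV.
#' @export
reversal_potential <- function(pipette, bath, rb_permeability = 1) {
  stopifnot(inherits(pipette, "ionic_solution"),
            inherits(bath, "ionic_solution"))
  cin <- .solution_conc(pipette, "K") +
    rb_permeability * .solution_conc(pipette, "Rb")
  cout <- .solution_conc(bath, "K") +
    rb_permeability * .solution_conc(bath, "Rb")
  if (cin <= 0 || cout <= 0)
    stop("permeant concentration must be positive on both sides")
  1000 * (.GAS_R * bath$temperature_K) / .FARADAY * log(cout / cin)
}

#' Liquid junction potential correction
#'
#' Converts amplifier command potentials to true membrane potentials with the
#' single sign convention used throughout the package:
#' \eqn{V_m = V_{cmd} - LJP}. With `ljp = 0` the correction is the identity.
#'
#' @param command_mV Command potential(s), mV.
#' @param bath An [ionic_solution()] carrying the LJP, or a bare LJP value
#'   in mV.
#' @return True membrane potential(s), mV.
#' @seealso [ljp_uncorrect()] for the inverse (membrane to command).
#' @export
ljp_correct <- function(command_mV, bath) {
  command_mV - .ljp_of(bath)
}

#' Inverse liquid junction potential correction
#'
#' Recovers the amplifier command potential that produces a desired true
#' membrane potential: \eqn{V_{cmd} = V_m + LJP}.
#'
#' @param membrane_mV Membrane potential(s), mV.
#' @inheritParams ljp_correct
#' @return Command potential(s), mV.
#' @export
ljp_uncorrect <- function(membrane_mV, bath) {
  membrane_mV + .ljp_of(bath)
}

.ljp_of <- function(bath) {
  if (inherits(bath, "ionic_solution")) return(bath$ljp_mV)
  if (is.numeric(bath) && length(bath) == 1L && is.finite(bath)) return(bath)
  stop("`bath` must be an ionic_solution or a single LJP value in mV")
}
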