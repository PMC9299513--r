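#' Instantaneous tail-current amplitudes
#'
#' Measures, per sweep, the tail current on return to the fixed tail
#' potential after each prepulse. The instantaneous amplitude is obtained
#' from the samples in a post-settling window after tail onset (default
#' 2-10 ms, dodging capacitive settling), either linearly extrapolated back
#' to the tail onset (default; removes the deactivation decay accrued inside
#' the window) or averaged as-is (`method = "window_mean"`).
#'
#' The returned amplitudes are baseline-referenced: the tail of the most
#' hyperpolarized prepulse -- where activation is (nearly) zero -- is
#' subtracted from every sweep, so leak and any standing current at the tail
#' potential cancel (`reference = "min_prepulse"`, the default).
#'
#' @param s A [sweep_set()] whose protocol has a tail segment.
#' @param window_ms `c(from, to)` window after tail onset, ms.
#' @param method `"extrapolate"` or `"window_mean"`.
#' @param reference `"min_prepulse"` or `"none"` (raw amplitudes).
#' @return Named numeric vector of tail amplitudes (pA); names are the
#'   LJP-corrected prepulse potentials. Attributes: `tail_mV` (corrected
#'   tail potential) and `reference_mV` (the reference prepulse, or `NA`).
#' @export
tail_current <- function(s, window_ms = c(2, 10),
                         method = c("extrapolate", "window_mean"),
                         reference = c("min_prepulse", "none")) {
  stopifnot(inherits(s, "sweep_set"))
  method <- match.arg(method)
  reference <- match.arg(reference)
  p <- s$protocol
  if (is.null(p$tail_mV)) stop("protocol lacks a tail segment")
  seg <- .segment_index(p)
  t_tail <- s$time_ms[seg$tail] - s$time_ms[seg$tail[1]]
  in_win <- t_tail >= window_ms[1] & t_tail <= window_ms[2]
  if (!any(in_win)) stop("empty tail measurement window")
  idx <- seg$tail[in_win]
  tloc <- t_tail[in_win]
  amps <- vapply(seq_len(ncol(s$sweeps)), function(j) {
    y <- s$sweeps[idx, j]
    if (method == "window_mean" || length(y) < 3) mean(y)
    else unname(stats::coef(stats::lm(y ~ tloc))[1])  # value at tail onset
  }, 0)
  v <- sweep_potentials(s)
  names(amps) <- as.character(v)
  ref_v <- NA_real_
  if (reference == "min_prepulse") {
    i0 <- which.min(v)
    ref_v <- v[i0]
    amps <- amps - amps[i0]
  }
  vt <- if (s$ljp_applied) p$tail_mV else ljp_correct(p$tail_mV, s$bath)
  structure(amps, tail_mV = vt, reference_mV = ref_v)
}

#' Tail conductance from a tail current
#'
#' \eqn{g = I_{tail} / (V_m - E_K)}: the tail amplitude divided by the K+
#' driving force at the tail potential. Units pA/mV = nS.
#'
#' @param i_tail_pA Tail amplitude(s), pA.
#' @param vm_mV Tail (membrane) potential, mV.
#' @param e_k_mV K+ reversal potential, mV.
#' @return Conductance(s), nS.
#' @export
tail_conductance <- function(i_tail_pA, vm_mV, e_k_mV) {
  if (any(vm_mV == e_k_mV))
    stop("undefined driving force: vm equals the reversal potential")
  i_tail_pA / (vm_mV - e_k_mV)
}

#' Conductance-voltage curve from tail currents
#'
#' Converts tail amplitudes to conductances via the driving force at the
#' tail potential and assembles the conductance-versus-prepulse-voltage (GV)
#' curve. `gmax_nS` is the largest tail conductance across prepulses (the
#' raw estimate; the fitted asymptote is additionally reported by
#' [fit_boltzmann()]).
#'
#' Two readings of the conductance bookkeeping are available. The default
#' (`mode = "tail"`) takes the tail conductance itself as the conductance
#' activated at each prepulse -- the tail amplitude is directly proportional
#' to the open fraction reached during the prepulse, which is the reading
#' validated by parameter recovery on simulated cells. `mode = "literal"`
#' instead reports the maximum conductance minus the tail conductance
#' (the deactivating component); the two coincide when that component is
#' referenced to the saturated tail.
#'
#' @param tails Named tail amplitudes from [tail_current()] (names =
#'   prepulse potentials, mV).
#' @param e_k_mV K+ reversal potential, mV.
#' @param tail_mV Tail potential; defaults to the `tail_mV` attribute.
#' @param mode `"tail"` or `"literal"`.
#' @return An object of class `gv_curve` with fields
#'   `prepulse_voltages_mV`, `tail_currents_pA`, `tail_conductances_nS`,
#'   `conductances_nS`, `gmax_nS`, `e_k_mV`, `tail_potential_mV` and the
#'   zero-activation `reference_mV` attribute (if any).
#' @export
gv_from_tails <- function(tails, e_k_mV, tail_mV = NULL,
                          mode = c("tail", "literal")) {
  mode <- match.arg(mode)
  if (is.null(tail_mV)) tail_mV <- attr(tails, "tail_mV")
  if (is.null(tail_mV)) stop("`tail_mV` is required")
  v <- as.numeric(names(tails))
  if (any(is.na(v))) stop("`tails` must be named by prepulse potential")
  if (length(v) < 5)
    stop("insufficient data: need at least 5 prepulse points")
  o <- order(v)
  v <- v[o]
  i_tail <- unname(tails[o])
  g_tail <- tail_conductance(i_tail, tail_mV, e_k_mV)
  gmax <- max(g_tail)
  g <- switch(mode, tail = g_tail, literal = gmax - g_tail)
  structure(
    list(prepulse_voltages_mV = v, tail_currents_pA = i_tail,
         tail_conductances_nS = g_tail, conductances_nS = g,
         gmax_nS = gmax, e_k_mV = e_k_mV, tail_potential_mV = tail_mV,
         mode = mode),
    reference_mV = attr(tails, "reference_mV"),
    class = "gv_curve")
}

#' @export
print.gv_curve <- function(x, ...) {
  cat(sprintf("<gv_curve> %d prepulses, gmax (raw) %.3g nS, E_K %.1f mV\n",
              length(x$prepulse_voltages_mV), x$gmax_nS, x$e_k_mV))
  print(data.frame(prepulse_mV = x$prepulse_voltages_mV,
                   tail_pA = x$tail_currents_pA,
                   g_nS = x$conductances_nS), row.names = FALSE)
  invisible(x)
}

.boltzmann <- function(v, vhalf, slope) 1 / (1 + exp((vhalf - v) / slope))

#' Boltzmann fit of a GV curve
#'
#' Nonlinear least-squares fit of the conductance-voltage data to the
#' Boltzmann activation curve
#' \eqn{g/g_{max} = 1/(1 + \exp((V_{1/2} - V)/S))}, yielding the
#' half-activation voltage, the slope factor and the fitted maximal
#' conductance.
#'
#' When the GV curve carries a zero-activation reference prepulse (see
#' [tail_current()]), the fitted model is by default the exact forward model
#' of that measurement, \eqn{g = g_{max}[B(V) - B(V_{ref})]}: the reference
#' subtraction removes the (small but, for shallow slopes, non-negligible)
#' activation still present at the most hyperpolarized prepulse, and
#' ignoring it would bias \eqn{g_{max}} and \eqn{V_{1/2}}. Pass
#' `reference_mV = NA` to force the plain Boltzmann.
#'
#' Fits are unweighted; starting values are the half-range crossing for
#' \eqn{V_{1/2}}, 15 mV for S and the largest conductance for
#' \eqn{g_{max}}; convergence tolerance 1e-10. Degenerate (flat) data are
#' flagged as non-converged with `NA` parameters and a warning.
#'
#' @param gv A [gv_curve()], or a data.frame/list with elements
#'   `prepulse_voltages_mV` (or `voltage`) and `conductances_nS` (or
#'   `conductance`).
#' @param reference_mV Zero-activation reference prepulse, `NA` for none.
#'   Defaults to the curve's recorded reference.
#' @return An object of class `boltzmann_fit`: `vhalf_mV`, `slope_mV`,
#'   `gmax_nS` (fitted asymptote), `residual_rms` (on the normalized g/gmax
#'   scale), `converged`, `n_points`.
#' @export
fit_boltzmann <- function(gv, reference_mV = NULL) {
  if (inherits(gv, "gv_curve")) {
    v <- gv$prepulse_voltages_mV
    g <- gv$conductances_nS
    if (is.null(reference_mV))
      reference_mV <- attr(gv, "reference_mV") %||% NA_real_
  } else {
    v <- gv$prepulse_voltages_mV %||% gv$voltage
    g <- gv$conductances_nS %||% gv$conductance
    if (is.null(reference_mV)) reference_mV <- NA_real_
  }
  if (length(v) < 5 || length(v) != length(g))
    stop("need at least 5 matched (voltage, conductance) points")
  bad_fit <- function(msg) {
    warning(paste0("Boltzmann fit not converged: ", msg))
    structure(list(vhalf_mV = NA_real_, slope_mV = NA_real_,
                   gmax_nS = NA_real_, residual_rms = NA_real_,
                   converged = FALSE, n_points = length(v)),
              class = "boltzmann_fit")
  }
  if (diff(range(g)) <= 1e-12 * max(abs(g), 1))
    return(bad_fit("flat conductance data (V1/2 and slope unidentifiable)"))

  gmax0 <- max(g)
  gn <- g / gmax0
  # half-range crossing for the V1/2 start value
  above <- gn >= 0.5
  vh0 <- if (any(above) && any(!above)) {
    i <- which(above)[1]
    if (i > 1) {
      stats::approx(gn[(i - 1):i], v[(i - 1):i], xout = 0.5)$y
    } else v[i]
  } else stats::median(v)
  if (!is.finite(vh0)) vh0 <- stats::median(v)

  dat <- data.frame(v = v, g = g)
  use_ref <- is.finite(reference_mV)
  form <- if (use_ref)
    g ~ gmax * (1 / (1 + exp((vhalf - v) / slope)) -
                1 / (1 + exp((vhalf - reference_mV) / slope)))
  else
    g ~ gmax / (1 + exp((vhalf - v) / slope))
  env <- environment()
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat,
                      start = list(gmax = gmax0 * 1.05, vhalf = vh0,
                                   slope = 15),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) return(bad_fit(conditionMessage(fit)))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["slope"]] <= 0)
    return(bad_fit("non-positive or non-finite slope"))
  rms <- sqrt(mean(stats::residuals(fit)^2)) / abs(cf[["gmax"]])
  structure(
    list(vhalf_mV = unname(cf[["vhalf"]]), slope_mV = unname(cf[["slope"]]),
         gmax_nS = unname(cf[["gmax"]]), residual_rms = rms,
         converged = TRUE, n_points = length(v)),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> V1/2 = %.2f mV, S = %.2f mV, gmax = %.3f nS (%s, n = %d, rms %.2g)\n",
    x$vhalf_mV, x$slope_mV, x$gmax_nS,
    if (x$converged) "converged" else "NOT converged", x$n_points,
    x$residual_rms))
  invisible(x)
}

#' Full tail-analysis pipeline for one cell
#'
#' Convenience wrapper running [tail_current()] -> [gv_from_tails()] ->
#' [fit_boltzmann()] on one tail-protocol sweep set, with E_K from the
#' configured solutions.
#'
#' @param s A [sweep_set()] recorded under a tail protocol.
#' @param pipette Pipette solution used for E_K (Nernst).
#' @param ... Passed to [tail_current()].
#' @return List with `tails`, `gv` and `fit`.
#' @export
tail_analysis <- function(s, pipette = pipette_preset(), ...) {
  e_k <- nernst_potential(pipette, s$bath)
  tails <- tail_current(s, ...)
  gv <- gv_from_tails(tails, e_k)
  list(tails = tails, gv = gv, fit = fit_boltzmann(gv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
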