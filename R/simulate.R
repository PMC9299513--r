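# Closed-form gating trajectory over the piecewise-constant voltage segments
# of one sweep. Under voltage clamp the gate ODE dm/dt = (m_inf(V) - m)/tau
# has the exact solution m(t) = m_inf + (m0 - m_inf) exp(-t/tau) within each
# segment (exponential-Euler integration is exact here), so gate values are
# evaluated analytically at the sample times.
.gate_trace <- function(v_seg, dur_seg, t_local, m0, vhalf, slope, tau,
                        increasing = TRUE) {
  out <- vector("list", length(v_seg))
  for (i in seq_along(v_seg)) {
    minf <- if (increasing) steady_state_open(v_seg[i], vhalf, slope)
            else 1 - steady_state_open(v_seg[i], vhalf, slope)
    out[[i]] <- minf + (m0 - minf) * exp(-t_local[[i]] / tau)
    m0 <- minf + (m0 - minf) * exp(-dur_seg[i] / tau)
  }
  unlist(out, use.names = FALSE)
}

# Current (pA) of one channel along one sweep. v is the full sample-wise
# membrane potential; v_seg/dur_seg/t_local describe the segments.
.channel_current <- function(ch, erev, v, v_seg, dur_seg, t_local) {
  if (ch$family == "kir") {
    open <- kir_rectification(v, ch$rect_vhalf_mV, ch$rect_slope_mV)
  } else {
    m0 <- steady_state_open(v_seg[1], ch$act_vhalf_mV, ch$act_slope_mV)
    open <- .gate_trace(v_seg, dur_seg, t_local, m0,
                        ch$act_vhalf_mV, ch$act_slope_mV, ch$act_tau_ms)
    if (ch$family == "a_type") {
      h0 <- 1 - steady_state_open(v_seg[1], ch$inact_vhalf_mV,
                                  ch$inact_slope_mV)
      h <- .gate_trace(v_seg, dur_seg, t_local, h0,
                       ch$inact_vhalf_mV, ch$inact_slope_mV,
                       ch$inact_tau_ms, increasing = FALSE)
      open <- open * h
    }
  }
  ch$gmax_nS * open * (v - erev)   # nS * mV = pA
}

# Run `expr` under a private RNG stream without disturbing the caller's.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Generates the episodic current traces of one cell under one protocol.
#' Gating variables follow first-order Hodgkin-Huxley kinetics integrated in
#' closed form (the command potential is piecewise constant, so the
#' exponential gate update is exact at any sample interval); gates start at
#' their steady state for the holding potential. The total current per sample
#' is the sum of the channel currents
#' \eqn{g_{max} m h\, r(V) (V - E_{rev})}, the ohmic leak, and additive
#' Gaussian recording noise seeded from the cell's seed (deterministic:
#' the same cell and protocol always produce identical sweeps).
#'
#' @param cell A [cell_spec()].
#' @param protocol A [voltage_protocol()].
#' @param bath Bath [ionic_solution()]. When `modifiers` contains `"rb"` and
#'   the bath is the Na+-based preset, the bath is swapped for the Rb+-based
#'   preset and reversal potentials are recomputed.
#' @param pipette Pipette [ionic_solution()] used for Nernst reversal
#'   potentials of channels whose `erev_mV` is `NA`.
#' @param modifiers Character vector of modifier names applied via
#'   [apply_modifier()] before simulating.
#' @param potentials `"membrane"` (default): the protocol's potentials are
#'   interpreted as true membrane potentials and the sweep set is marked
#'   `ljp_applied`. `"command"`: they are amplifier commands, the membrane
#'   sees [ljp_correct()] of them, and the analysis must correct.
#' @param rb_permeability Rb+/K+ permeability ratio for reversal potentials.
#' @param noise Set `FALSE` to suppress the noise term regardless of the
#'   cell's `noise_sd_pA`.
#' @return A [sweep_set()].
#' @export
simulate_sweeps <- function(cell, protocol, bath, pipette = pipette_preset(),
                            modifiers = character(),
                            potentials = c("membrane", "command"),
                            rb_permeability = 1, noise = TRUE) {
  stopifnot(inherits(cell, "cell_spec"), inherits(protocol, "voltage_protocol"),
            inherits(bath, "ionic_solution"))
  potentials <- match.arg(potentials)
  for (m in modifiers) cell <- apply_modifier(cell, m)
  if ("rb" %in% modifiers && identical(bath$name, "na_based"))
    bath <- bath_preset("rb_based", temperature_K = bath$temperature_K)

  bad <- vapply(cell$channels, function(ch) {
    pars <- unlist(ch[c("gmax_nS", "act_vhalf_mV", "act_slope_mV",
                        "act_tau_ms", "inact_vhalf_mV", "inact_slope_mV",
                        "inact_tau_ms", "rect_vhalf_mV", "rect_slope_mV")])
    any(!is.finite(pars))
  }, TRUE)
  if (any(bad)) stop("simulation error: non-finite channel parameters")

  cmd <- protocol_sweeps(protocol)
  to_vm <- function(v) if (potentials == "membrane") v else ljp_correct(v, bath)
  vm_step <- to_vm(cmd)
  vm_hold <- to_vm(protocol$holding_mV)
  has_tail <- !is.null(protocol$tail_mV)
  vm_tail <- if (has_tail) to_vm(protocol$tail_mV) else NULL

  erev <- vapply(cell$channels, function(ch) {
    if (is.finite(ch$erev_mV)) ch$erev_mV
    else reversal_potential(pipette, bath, rb_permeability)
  }, 0)

  dt <- protocol$sample_interval_ms
  nseg <- .segment_counts(protocol)
  nseg <- nseg[nseg > 0]
  n <- sum(nseg)
  time_ms <- (seq_len(n) - 1) * dt
  # local time within each segment; first sample of a segment sits at its start
  t_local <- lapply(nseg, function(k) (seq_len(k) - 1) * dt)
  dur_seg <- nseg * dt

  traces <- matrix(0, n, length(cmd))
  for (j in seq_along(cmd)) {
    v_seg <- c(vm_hold, vm_step[j], vm_tail)[seq_along(nseg)]
    v <- rep(v_seg, times = nseg)
    i_tot <- cell$leak_conductance_nS * (v - cell$leak_erev_mV)
    for (k in seq_along(cell$channels))
      i_tot <- i_tot + .channel_current(cell$channels[[k]], erev[k], v,
                                        v_seg, dur_seg, t_local)
    traces[, j] <- i_tot
  }
  if (noise && cell$noise_sd_pA > 0) {
    traces <- traces + .with_seed(cell$seed,
      matrix(stats::rnorm(length(traces), 0, cell$noise_sd_pA), n))
  }
  sweep_set(time_ms, traces, cmd, protocol, bath, cell_id = cell$cell_id,
            ljp_applied = potentials == "membrane")
}
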