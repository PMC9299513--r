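#' Episodic voltage-step protocol
#'
#' One holding potential plus a family of test steps and an optional fixed
#' tail step, defining one episodic voltage-clamp stimulation. Sweeps run
#' holding -> test step -> (tail), one sweep per test potential.
#'
#' @param holding_mV Holding potential, mV.
#' @param step_start_mV,step_stop_mV First and last test potentials, mV.
#' @param step_increment_mV Step increment, mV. Must divide
#'   `step_stop_mV - step_start_mV` exactly.
#' @param step_duration_ms Test step duration, ms.
#' @param holding_duration_ms Pre-step holding segment recorded with each
#'   sweep (used for baseline estimation), ms.
#' @param tail_mV,tail_duration_ms Optional fixed tail step appended after the
#'   test step (both must be given together).
#' @param sample_interval_ms Sampling interval, ms. Must be smaller than the
#'   step duration.
#'
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mV, step_start_mV, step_stop_mV,
                             step_increment_mV = 10, step_duration_ms,
                             holding_duration_ms = 50,
                             tail_mV = NULL, tail_duration_ms = NULL,
                             sample_interval_ms = 0.1) {
  nums <- c(holding_mV, step_start_mV, step_stop_mV, step_increment_mV,
            step_duration_ms, holding_duration_ms, sample_interval_ms)
  if (any(!is.finite(nums)))
    stop("protocol parameters must be finite numbers")
  if (step_duration_ms <= 0 || holding_duration_ms <= 0 ||
      sample_interval_ms <= 0)
    stop("durations and the sample interval must be positive")
  if (sample_interval_ms >= step_duration_ms)
    stop("`sample_interval_ms` must be smaller than the step duration")
  if (is.null(tail_mV) != is.null(tail_duration_ms))
    stop("`tail_mV` and `tail_duration_ms` must be given together")
  if (!is.null(tail_duration_ms) && tail_duration_ms <= 0)
    stop("`tail_duration_ms` must be positive")
  span <- step_stop_mV - step_start_mV
  if (span != 0) {
    if (step_increment_mV == 0)
      stop("invalid protocol: zero increment over a non-zero step range")
    k <- span / step_increment_mV
    if (k < 0 || abs(k - round(k)) > 1e-9)
      stop("invalid protocol: increment does not divide the step range")
  }
  structure(
    list(holding_mV = holding_mV, step_start_mV = step_start_mV,
         step_stop_mV = step_stop_mV, step_increment_mV = step_increment_mV,
         step_duration_ms = step_duration_ms,
         holding_duration_ms = holding_duration_ms,
         tail_mV = tail_mV, tail_duration_ms = tail_duration_ms,
         sample_interval_ms = sample_interval_ms),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol> hold %g mV (%g ms), steps %g..%g by %g mV (%g ms)",
    x$holding_mV, x$holding_duration_ms, x$step_start_mV, x$step_stop_mV,
    x$step_increment_mV, x$step_duration_ms))
  if (!is.null(x$tail_mV))
    cat(sprintf(", tail %g mV (%g ms)", x$tail_mV, x$tail_duration_ms))
  cat(sprintf(", dt %g ms, %d sweeps\n", x$sample_interval_ms,
              length(protocol_sweeps(x))))
  invisible(x)
}

#' Ordered list of test (command) potentials of a protocol
#'
#' @param p A [voltage_protocol()].
#' @return Numeric vector `start, start + inc, ..., stop` (a single value when
#'   start equals stop).
#' @export
protocol_sweeps <- function(p) {
  stopifnot(inherits(p, "voltage_protocol"))
  if (p$step_stop_mV == p$step_start_mV) return(p$step_start_mV)
  n <- round((p$step_stop_mV - p$step_start_mV) / p$step_increment_mV)
  p$step_start_mV + (0:n) * p$step_increment_mV
}

#' Voltage-protocol presets
#'
#' The four stimulation families used for RPE K+ current characterisation:
#'
#' * `"outward_50ms"`: 50 ms pulses, -45 to +45 mV in 10 mV increments, from a
#'   -45 mV holding potential (delayed-rectifier survey).
#' * `"sustained_1000ms"`: 1000 ms pulses, -70 to +40 mV in 10 mV steps, from
#'   -70 mV (M-current / A-type survey).
#' * `"tail_gv"`: from a -10 mV holding potential, 1000 ms prepulses -100 to
#'   +40 mV in 10 mV steps, tail at -10 mV (tail-current conductance
#'   analysis).
#' * `"tail_gv_deep"`: as `"tail_gv"` but prepulses from -140 mV.
#' * `"kir_iv"`: 100 ms steps from -145 to +45 mV in 10 mV intervals, from a
#'   -45 mV holding potential (inward-rectifier survey).
#'
#' @param name Preset name.
#' @param sample_interval_ms Sampling interval, ms.
#' @return A [voltage_protocol()].
#' @export
protocol_preset <- function(name = c("outward_50ms", "sustained_1000ms",
                                     "tail_gv", "tail_gv_deep", "kir_iv"),
                            sample_interval_ms = 0.1) {
  name <- match.arg(name)
  switch(name,
    outward_50ms = voltage_protocol(-45, -45, 45, 10, 50,
      sample_interval_ms = sample_interval_ms),
    sustained_1000ms = voltage_protocol(-70, -70, 40, 10, 1000,
      sample_interval_ms = sample_interval_ms),
    tail_gv = voltage_protocol(-10, -100, 40, 10, 1000,
      tail_mV = -10, tail_duration_ms = 500,
      sample_interval_ms = sample_interval_ms),
    tail_gv_deep = voltage_protocol(-10, -140, 40, 10, 1000,
      tail_mV = -10, tail_duration_ms = 500,
      sample_interval_ms = sample_interval_ms),
    kir_iv = voltage_protocol(-45, -145, 45, 10, 100,
      sample_interval_ms = sample_interval_ms))
}
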