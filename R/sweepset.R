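#' Episodic sweep set
#'
#' One cell's current traces for one protocol: a shared time grid, one trace
#' per command potential (columns of `sweeps`), and the protocol/solution
#' metadata needed by the analysis.
#'
#' @param time_ms Strictly increasing sample times, ms, starting at the
#'   beginning of the pre-step holding segment.
#' @param sweeps Numeric matrix, `length(time_ms)` rows, one column per
#'   command potential, pA.
#' @param command_potentials_mV Ordered command potentials, one per column.
#' @param protocol The [voltage_protocol()] that produced the sweeps.
#' @param bath The bath [ionic_solution()].
#' @param cell_id Cell identifier.
#' @param ljp_applied `TRUE` when `command_potentials_mV` (and the protocol's
#'   potentials) are already true membrane potentials; `FALSE` when they are
#'   amplifier commands still requiring [ljp_correct()].
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(time_ms, sweeps, command_potentials_mV, protocol, bath,
                      cell_id = "cell", ljp_applied = FALSE) {
  sweeps <- as.matrix(sweeps)
  if (length(time_ms) != nrow(sweeps))
    stop("`time_ms` must match the rows of `sweeps`")
  if (length(command_potentials_mV) != ncol(sweeps))
    stop("need exactly one trace per command potential")
  if (any(diff(time_ms) <= 0))
    stop("`time_ms` must be strictly increasing")
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(bath, "ionic_solution"))
  colnames(sweeps) <- as.character(command_potentials_mV)
  structure(
    list(time_ms = as.numeric(time_ms), sweeps = sweeps,
         command_potentials_mV = as.numeric(command_potentials_mV),
         protocol = protocol, bath = bath, cell_id = as.character(cell_id),
         ljp_applied = isTRUE(ljp_applied)),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %s: %d sweeps x %d samples (dt %g ms), bath %s, %s\n",
    x$cell_id, ncol(x$sweeps), nrow(x$sweeps),
    x$protocol$sample_interval_ms, x$bath$name,
    if (x$ljp_applied) "membrane potentials" else "command potentials"))
  invisible(x)
}

#' Analysis (LJP-corrected) potentials of a sweep set
#'
#' @param s A [sweep_set()].
#' @return The true membrane potentials of the sweeps, mV.
#' @export
sweep_potentials <- function(s) {
  stopifnot(inherits(s, "sweep_set"))
  if (s$ljp_applied) s$command_potentials_mV
  else ljp_correct(s$command_potentials_mV, s$bath)
}

# Segment sample counts (holding / step / tail) of a protocol.
.segment_counts <- function(p) {
  dt <- p$sample_interval_ms
  c(hold = round(p$holding_duration_ms / dt),
    step = round(p$step_duration_ms / dt),
    tail = if (is.null(p$tail_mV)) 0L else round(p$tail_duration_ms / dt))
}

# Sample indices of the three segments of a sweep.
.segment_index <- function(p) {
  n <- .segment_counts(p)
  list(hold = seq_len(n[["hold"]]),
       step = n[["hold"]] + seq_len(n[["step"]]),
       tail = if (n[["tail"]] > 0)
         n[["hold"]] + n[["step"]] + seq_len(n[["tail"]]) else integer(0))
}
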