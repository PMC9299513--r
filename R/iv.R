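#' Per-sweep summary current
#'
#' Reduces each sweep of a sweep set to one baseline-subtracted current.
#' The baseline is the mean current over the final 50% of the pre-step
#' holding segment (avoids settling transients). Measures:
#'
#' * `"peak"`: the signed extremum of the baseline-subtracted current with
#'   the largest absolute excursion inside the window (captures outward Kv
#'   peaks and inward Kir peaks with one rule);
#' * `"end_of_step"`: the baseline-subtracted mean over the final 10% of the
#'   step (or of the window, when one is given).
#'
#' @param s A [sweep_set()].
#' @param measure `"peak"` or `"end_of_step"`.
#' @param window_ms Optional `c(from, to)` interval in ms, measured from step
#'   onset, within which the measure is taken. Default: the whole step.
#' @param baseline Set `FALSE` for raw (absolute) currents without baseline
#'   subtraction, e.g. when comparing amplitudes across baths whose holding
#'   currents differ.
#' @return Named numeric vector, one summary current (pA) per sweep; names
#'   are the command potentials.
#' @export
summary_current <- function(s, measure = c("peak", "end_of_step"),
                            window_ms = NULL, baseline = TRUE) {
  stopifnot(inherits(s, "sweep_set"))
  measure <- match.arg(measure)
  seg <- .segment_index(s$protocol)
  t_step <- s$time_ms[seg$step] - s$time_ms[seg$step[1]]
  if (is.null(window_ms)) window_ms <- range(t_step)
  if (length(window_ms) != 2 || diff(window_ms) < 0)
    stop("`window_ms` must be an interval c(from, to)")
  in_win <- seg$step[t_step >= window_ms[1] & t_step <= window_ms[2]]
  if (length(in_win) == 0) stop("empty measurement window")
  base_idx <- seg$hold[seg$hold > length(seg$hold) / 2]
  out <- vapply(seq_len(ncol(s$sweeps)), function(j) {
    tr <- s$sweeps[, j]
    b <- if (baseline) mean(tr[base_idx]) else 0
    x <- tr[in_win] - b
    switch(measure,
      peak = x[which.max(abs(x))],
      end_of_step = {
        k <- max(1L, ceiling(0.1 * length(x)))
        mean(x[(length(x) - k + 1):length(x)])
      })
  }, 0)
  names(out) <- as.character(s$command_potentials_mV)
  out
}

#' IV curve container
#'
#' @param voltages_mV Strictly increasing LJP-corrected potentials.
#' @param currents_pA Summary current per potential.
#' @param measure `"peak"` or `"end_of_step"`.
#' @param n Number of cells averaged (1 for a single cell).
#' @param sem_pA Optional per-point SEM.
#' @param normalized Logical flag.
#' @param reference_mV Normalization reference potential (if normalized).
#' @return An object of class `iv_curve`.
#' @export
iv_curve <- function(voltages_mV, currents_pA, measure = "peak", n = 1L,
                     sem_pA = NULL, normalized = FALSE,
                     reference_mV = NA_real_) {
  if (length(voltages_mV) != length(currents_pA))
    stop("voltages and currents must have equal length")
  if (any(diff(voltages_mV) <= 0))
    stop("voltages must be strictly increasing")
  structure(
    list(voltages_mV = as.numeric(voltages_mV),
         currents_pA = as.numeric(currents_pA), measure = measure,
         n = as.integer(n), sem_pA = sem_pA, normalized = isTRUE(normalized),
         reference_mV = reference_mV),
    class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d points (%s%s, n = %d)\n",
              length(x$voltages_mV), x$measure,
              if (x$normalized) sprintf(", normalized at %g mV",
                                        x$reference_mV) else "", x$n))
  df <- data.frame(voltage_mV = x$voltages_mV, current = x$currents_pA)
  if (!is.null(x$sem_pA)) df$sem <- x$sem_pA
  print(df, row.names = FALSE)
  invisible(x)
}

#' Build a single-cell IV curve from a sweep set
#'
#' Applies the LJP correction to every command potential (unless the sweep
#' set already holds membrane potentials) and takes one [summary_current()]
#' per sweep, with the same window for all sweeps.
#'
#' @inheritParams summary_current
#' @return An [iv_curve()] with `n = 1`.
#' @export
build_iv <- function(s, measure = c("peak", "end_of_step"),
                     window_ms = NULL) {
  measure <- match.arg(measure)
  iv_curve(sweep_potentials(s), summary_current(s, measure, window_ms),
           measure = measure, n = 1L)
}

#' Normalize an IV curve at a reference potential
#'
#' Divides all currents (and SEMs) by the absolute current at the reference
#' potential, which therefore maps to +/-1. Normalizing twice at the same
#' reference is the identity.
#'
#' @param iv An [iv_curve()].
#' @param reference_mV Reference potential; must be present in the curve with
#'   a nonzero current.
#' @return A normalized [iv_curve()].
#' @export
normalize_iv <- function(iv, reference_mV) {
  stopifnot(inherits(iv, "iv_curve"))
  i <- which(abs(iv$voltages_mV - reference_mV) < 1e-6)
  if (length(i) != 1)
    stop("reference potential not present in the curve")
  ref <- abs(iv$currents_pA[i])
  if (ref == 0) stop("zero current at the reference potential")
  iv$currents_pA <- iv$currents_pA / ref
  if (!is.null(iv$sem_pA)) iv$sem_pA <- iv$sem_pA / ref
  iv$normalized <- TRUE
  iv$reference_mV <- reference_mV
  iv
}

#' Pointwise average of IV curves
#'
#' Mean and SEM (sample SD / sqrt(n)) per voltage across cells. All curves
#' must share the voltage grid. With a single curve the SEM is reported as 0
#' with a warning.
#'
#' @param curves List of [iv_curve()] objects on identical voltage grids.
#' @return An [iv_curve()] with `n = length(curves)` and per-point SEM.
#' @export
average_ivs <- function(curves) {
  if (!length(curves)) stop("no curves to average")
  stopifnot(all(vapply(curves, inherits, TRUE, "iv_curve")))
  v <- curves[[1]]$voltages_mV
  for (cv in curves)
    if (length(cv$voltages_mV) != length(v) ||
        any(abs(cv$voltages_mV - v) > 1e-6))
      stop("mismatched voltage grids")
  mat <- vapply(curves, `[[`, v, "currents_pA")
  mat <- matrix(mat, nrow = length(v))
  n <- length(curves)
  if (n == 1) {
    warning("single curve: SEM reported as 0")
    sem <- rep(0, length(v))
  } else {
    sem <- apply(mat, 1, stats::sd) / sqrt(n)
  }
  iv_curve(v, rowMeans(mat), measure = curves[[1]]$measure, n = n,
           sem_pA = sem, normalized = curves[[1]]$normalized,
           reference_mV = curves[[1]]$reference_mV)
}

#' Percent change of a current amplitude under an intervention
#'
#' \eqn{100 (|I_{test}| - |I_{control}|) / |I_{control}|}: negative for
#' block, positive for enhancement, for outward and inward currents alike
#' (an enhanced inward current grows more negative but its amplitude grows).
#' Both currents must be measured at the same corrected potential; a sign
#' change between control and test (current crossing its reversal) makes
#' the amplitude comparison meaningless and triggers a warning.
#'
#' @param i_control,i_test Currents in pA at the same corrected potential.
#' @return Percent change of the amplitude.
#' @examples
#' percent_change(100, 21)    # -79: a 79% block
#' percent_change(-10, -41.9) # +319: a 319% enhancement
#' @export
percent_change <- function(i_control, i_test) {
  if (any(i_control == 0)) stop("zero control current")
  if (any(sign(i_test) * sign(i_control) < 0))
    warning("control and test currents differ in sign")
  100 * (abs(i_test) - abs(i_control)) / abs(i_control)
}
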