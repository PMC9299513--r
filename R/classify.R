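#' Classification criteria
#'
#' Configurable rules by which a cell's recordings are assigned current-type
#' labels. Two methods are available:
#'
#' * `"template"` (default): matched-template regression. Each cell's
#'   concatenated sweeps are projected by least squares onto the
#'   unit-conductance current templates of the four channel-family presets
#'   (simulated noiselessly under the cell's own protocols), plus an ohmic
#'   leak pair (the voltage trace and a constant). A family is assigned when
#'   its fitted conductance exceeds `g_threshold_nS`. This detector uses the
#'   kinetics of the shipped presets (configurable through `templates`) and
#'   separates co-expressed current types cleanly, which simple amplitude
#'   thresholds cannot.
#' * `"threshold"`: interpretable per-family amplitude/kinetic rules:
#'   delayed rectifier if the baseline-subtracted outward current at the most
#'   depolarized short-protocol step exceeds `amplitude_threshold_pA`;
#'   a_type if, on the long protocol, the peak exceeds the threshold and
#'   end-of-step/peak < `inactivation_ratio`; m_current if the end-of-step
#'   current exceeds the threshold, end-of-step/peak > `sustain_ratio`, and
#'   the late/early half-step ratio exceeds 1 (slow activation); kir if the
#'   inward current at -145 mV exceeds the threshold and its magnitude
#'   exceeds `rectification_factor` times the outward current at +45 mV.
#'
#' All defaults are explicit assumptions: the amplitude threshold is 5x the
#' default 3 pA noise SD, the conductance threshold 0.1 nS.
#'
#' @param method `"template"` or `"threshold"`.
#' @param g_threshold_nS Conductance detection threshold (template method).
#' @param amplitude_threshold_pA Amplitude detection threshold (threshold
#'   method).
#' @param inactivation_ratio,sustain_ratio,rectification_factor Threshold
#'   method tuning constants.
#' @param templates Named list of unit-conductance [channel_model()]s used by
#'   the template method.
#' @return An object of class `classification_criteria`.
#' @export
classification_criteria <- function(method = c("template", "threshold"),
                                    g_threshold_nS = 0.1,
                                    amplitude_threshold_pA = 15,
                                    inactivation_ratio = 0.2,
                                    sustain_ratio = 0.8,
                                    rectification_factor = 2,
                                    templates = NULL) {
  method <- match.arg(method)
  if (is.null(templates))
    templates <- lapply(stats::setNames(nm = .channel_families),
                        function(f) channel_preset(f, gmax_nS = 1))
  structure(
    list(method = method, g_threshold_nS = g_threshold_nS,
         amplitude_threshold_pA = amplitude_threshold_pA,
         inactivation_ratio = inactivation_ratio,
         sustain_ratio = sustain_ratio,
         rectification_factor = rectification_factor,
         templates = templates),
    class = "classification_criteria")
}

#' Precompute the template design for a protocol set
#'
#' Builds the least-squares design used by the template classification
#' method: one column per channel-family template (unit conductance,
#' noiseless, simulated under the same protocols, baths and potential
#' convention as the supplied sweep sets), one column holding the membrane
#' potential trace and one intercept column. The QR decomposition is cached
#' so cohorts sharing protocols pay the simulation cost once.
#'
#' @param sweepsets List of [sweep_set()]s of one cell (one per protocol).
#' @param criteria A [classification_criteria()].
#' @param pipette Pipette solution for template reversal potentials.
#' @return A list with the design `qr`, the template `families` and the
#'   matrix column count, for use by [classify_cell()].
#' @export
template_design <- function(sweepsets, criteria = classification_criteria(),
                            pipette = pipette_preset()) {
  fams <- names(criteria$templates)
  cols <- lapply(fams, function(f) {
    unlist(lapply(sweepsets, function(s) {
      cl <- cell_spec(channels = list(criteria$templates[[f]]),
                      leak_conductance_nS = 0, noise_sd_pA = 0)
      tpl <- simulate_sweeps(
        cl, s$protocol, s$bath, pipette = pipette, noise = FALSE,
        potentials = if (s$ljp_applied) "membrane" else "command")
      as.vector(tpl$sweeps)
    }))
  })
  vtrace <- unlist(lapply(sweepsets, function(s) {
    p <- s$protocol
    nseg <- .segment_counts(p)
    nseg <- nseg[nseg > 0]
    vm <- sweep_potentials(s)
    vh <- if (s$ljp_applied) p$holding_mV else ljp_correct(p$holding_mV, s$bath)
    vt <- if (is.null(p$tail_mV)) NULL
          else if (s$ljp_applied) p$tail_mV else ljp_correct(p$tail_mV, s$bath)
    as.vector(vapply(vm, function(v)
      rep(c(vh, v, vt)[seq_along(nseg)], times = nseg),
      numeric(sum(nseg))))
  }))
  x <- cbind(do.call(cbind, cols), vtrace, 1)
  colnames(x) <- c(fams, "leak_v", "leak_const")
  list(qr = qr(x), families = fams, n = nrow(x))
}

.concat_sweeps <- function(sweepsets)
  unlist(lapply(sweepsets, function(s) as.vector(s$sweeps)))

# Reference amplitudes per detected family: outward families at the most
# depolarized available potential (+45 mV when present), kir at the most
# hyperpolarized (-145 mV when present).
.reference_amplitudes <- function(sweepsets, labels) {
  amp <- list()
  for (f in labels) {
    pick <- NULL; want <- NULL
    for (s in sweepsets) {
      v <- sweep_potentials(s)
      cand <- if (f == "kir") min(v) else max(v)
      better <- is.null(want) ||
        (f == "kir" && cand < want) || (f != "kir" && cand > want)
      if (better) { want <- cand; pick <- s }
    }
    sc <- summary_current(pick, "peak")
    v <- sweep_potentials(pick)
    i <- if (f == "kir") which.min(v) else which.max(v)
    amp[[f]] <- stats::setNames(unname(sc[i]), format(v[i]))
  }
  amp
}

#' Classify a cell by current phenotype
#'
#' Assigns a subset of `{delayed_rectifier, m_current, a_type, kir}` to one
#' cell from its per-protocol recordings, using the configured
#' [classification_criteria()]. Amplitudes at the reference potentials
#' (most depolarized step for outward families, most hyperpolarized for kir)
#' are reported for the assigned labels only.
#'
#' @param sweepsets List of [sweep_set()]s of one cell.
#' @param criteria A [classification_criteria()].
#' @param pipette Pipette solution (template method).
#' @param design Optional precomputed [template_design()] (cohorts).
#' @return An object of class `detection_result`: `cell_id`, `labels`,
#'   `gmax_nS` (template method fitted conductances) and
#'   `amplitude_at_reference_pA`.
#' @export
classify_cell <- function(sweepsets, criteria = classification_criteria(),
                          pipette = pipette_preset(), design = NULL) {
  if (inherits(sweepsets, "sweep_set")) sweepsets <- list(sweepsets)
  stopifnot(all(vapply(sweepsets, inherits, TRUE, "sweep_set")))
  cell_id <- sweepsets[[1]]$cell_id
  if (criteria$method == "template") {
    if (is.null(design))
      design <- template_design(sweepsets, criteria, pipette)
    y <- .concat_sweeps(sweepsets)
    if (length(y) != design$n)
      stop("design does not match the supplied sweep sets")
    coefs <- qr.coef(design$qr, y)
    g <- pmax(coefs[design$families], 0)
    labels <- design$families[g > criteria$g_threshold_nS]
    gmax <- g
  } else {
    labels <- .threshold_classify(sweepsets, criteria)
    gmax <- NULL
  }
  structure(
    list(cell_id = cell_id, labels = labels, gmax_nS = gmax,
         amplitude_at_reference_pA =
           .reference_amplitudes(sweepsets, labels)),
    class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: {%s}\n", x$cell_id,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# The interpretable amplitude/kinetics rules. Protocol roles are recognised
# structurally: "short" = step duration <= 100 ms reaching >= +40 mV;
# "long" = duration >= 500 ms; "kir" = most negative step <= -140 mV.
.threshold_classify <- function(sweepsets, criteria) {
  thr <- criteria$amplitude_threshold_pA
  labels <- character(0)
  find <- function(test) {
    for (s in sweepsets) if (isTRUE(test(s))) return(s)
    NULL
  }
  short <- find(function(s) s$protocol$step_duration_ms <= 100 &&
                  max(sweep_potentials(s)) >= 40)
  long <- find(function(s) s$protocol$step_duration_ms >= 500 &&
                 is.null(s$protocol$tail_mV))
  kirp <- find(function(s) min(sweep_potentials(s)) <= -140)
  if (is.null(short) || is.null(kirp))
    warning("partial classification: short outward and/or kir protocol missing")

  if (!is.null(short)) {
    # end-of-step mean: the rectifier is sustained over 50 ms and the
    # windowed mean is robust to the noise extremes a peak picks up
    eos <- summary_current(short, "end_of_step")
    v <- sweep_potentials(short)
    if (eos[which.max(v)] > thr) labels <- c(labels, "delayed_rectifier")
  }
  if (!is.null(long)) {
    v <- sweep_potentials(long)
    j <- which.max(v)
    pk <- summary_current(long, "peak")[j]
    eos <- summary_current(long, "end_of_step")[j]
    if (pk > thr && eos / pk < criteria$inactivation_ratio)
      labels <- c(labels, "a_type")
    half <- long$protocol$step_duration_ms / 2
    early <- summary_current(long, "end_of_step", window_ms = c(0, half))[j]
    if (eos > thr && eos / pk > criteria$sustain_ratio &&
        eos / max(early, .Machine$double.eps) > 1)
      labels <- c(labels, "m_current")
  }
  if (!is.null(kirp)) {
    v <- sweep_potentials(kirp)
    eos <- summary_current(kirp, "end_of_step")
    i_lo <- eos[which.min(v)]
    i_hi <- eos[which.max(v)]
    if (i_lo < -thr &&
        abs(i_lo) > criteria$rectification_factor * abs(i_hi))
      labels <- c(labels, "kir")
  }
  labels
}
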