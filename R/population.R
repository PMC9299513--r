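.default_incidence <- c(delayed_rectifier = 0.80, m_current = 0.22,
                        a_type = 0.15, kir = 0.14)

#' Default per-family conductance distributions
#'
#' Log-normal location/scale per family, parameterised so that the
#' distribution mean equals the preset conductance of the family and the
#' coefficient of variation is ~30% (`sdlog = 0.3`). The printed amplitude
#' spreads of the recordings are wider, but they fold in cell-size and access
#' variability that the ideal-clamp simulator does not model.
#'
#' @param sdlog Log-scale SD shared by the families.
#' @return data.frame with columns `family`, `meanlog`, `sdlog`.
#' @export
default_gmax_distribution <- function(sdlog = 0.3) {
  means <- vapply(.channel_families,
                  function(f) .channel_defaults[[f]]$gmax_nS, 0)
  data.frame(family = .channel_families,
             meanlog = log(means) - sdlog^2 / 2,
             sdlog = sdlog, row.names = NULL)
}

#' Heterogeneous-population specification
#'
#' Defines a cohort of simulated cells: each channel family is present in a
#' cell independently with its incidence probability; conductances and
#' capacitances are drawn from log-normal distributions; everything is
#' reproducible from one master seed (per-cell noise streams are derived
#' deterministically from it).
#'
#' @param n_cells Number of cells (>= 1).
#' @param incidence Named probabilities in `[0, 1]` per channel family.
#'   Defaults to the observed incidences 0.80 / 0.22 / 0.15 / 0.14 for the
#'   delayed rectifier, M-current, A-type and kir families.
#' @param gmax_distribution data.frame as returned by
#'   [default_gmax_distribution()].
#' @param capacitance_meanlog,capacitance_sdlog Log-normal parameters of the
#'   cell capacitance; defaults give a mean of 27 pF.
#' @param leak_conductance_nS,leak_erev_mV,noise_sd_pA Passed to each
#'   [cell_spec()].
#' @param seed Master seed of the cohort.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, incidence = .default_incidence,
                            gmax_distribution = default_gmax_distribution(),
                            capacitance_meanlog = log(27) - 0.35^2 / 2,
                            capacitance_sdlog = 0.35,
                            leak_conductance_nS = 0.5, leak_erev_mV = -20,
                            noise_sd_pA = 3, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("`n_cells` must be >= 1")
  incidence <- incidence[.channel_families]
  names(incidence) <- .channel_families
  incidence[is.na(incidence)] <- 0
  if (any(incidence < 0 | incidence > 1))
    stop("incidence probabilities must lie in [0, 1]")
  structure(
    list(n_cells = as.integer(n_cells), incidence = incidence,
         gmax_distribution = gmax_distribution,
         capacitance_meanlog = capacitance_meanlog,
         capacitance_sdlog = capacitance_sdlog,
         leak_conductance_nS = leak_conductance_nS,
         leak_erev_mV = leak_erev_mV, noise_sd_pA = noise_sd_pA,
         seed = as.integer(seed)),
    class = "population_spec")
}

# Draw the per-cell composition of a cohort (presence, conductances,
# capacitances, derived seeds) under the spec's master seed.
.draw_cohort <- function(spec) {
  fams <- .channel_families
  gd <- spec$gmax_distribution
  .with_seed(spec$seed, {
    present <- sapply(fams, function(f)
      stats::runif(spec$n_cells) < spec$incidence[[f]])
    present <- matrix(present, nrow = spec$n_cells,
                      dimnames = list(NULL, fams))
    gmax <- sapply(fams, function(f) {
      row <- gd[gd$family == f, ]
      stats::rlnorm(spec$n_cells, row$meanlog, row$sdlog)
    })
    cap <- stats::rlnorm(spec$n_cells, spec$capacitance_meanlog,
                         spec$capacitance_sdlog)
    seeds <- sample.int(.Machine$integer.max - 1L, spec$n_cells)
    list(present = present, gmax = gmax, capacitance = cap, seeds = seeds)
  })
}

# Build the cell_spec of one cohort member.
.cohort_cell <- function(spec, draw, i) {
  fams <- .channel_families[draw$present[i, ]]
  channels <- lapply(fams, function(f)
    channel_preset(f, gmax_nS = draw$gmax[i, f]))
  cell_spec(channels = channels, capacitance_pF = draw$capacitance[i],
            leak_conductance_nS = spec$leak_conductance_nS,
            leak_erev_mV = spec$leak_erev_mV,
            noise_sd_pA = spec$noise_sd_pA, seed = draw$seeds[i],
            cell_id = sprintf("cell%04d", i))
}

#' Generate a cohort of heterogeneous simulated cells
#'
#' Draws the cohort defined by a [population_spec()] and (optionally)
#' simulates every cell under every protocol. The returned ground-truth label
#' table makes blinded recovery testing possible.
#'
#' @param spec A [population_spec()].
#' @param protocols List of [voltage_protocol()] objects (named or not).
#' @param bath Bath [ionic_solution()] shared by the protocols, or a list of
#'   baths of the same length as `protocols`.
#' @param pipette Pipette solution.
#' @param keep_traces If `FALSE`, only cell specs and truth labels are
#'   returned (no simulation) -- useful for very large cohorts analysed
#'   streamingly, e.g. by [cohort_study()].
#' @return A list with elements `cells` (list of [cell_spec()]), `sweeps`
#'   (per cell, a list of [sweep_set()]s, or `NULL`), `truth` (data.frame of
#'   logical presence per family plus capacitance and true conductances) and
#'   `spec`.
#' @export
generate_population <- function(spec, protocols, bath,
                                pipette = pipette_preset(),
                                keep_traces = TRUE) {
  stopifnot(inherits(spec, "population_spec"))
  if (inherits(protocols, "voltage_protocol")) protocols <- list(protocols)
  baths <- if (inherits(bath, "ionic_solution"))
    rep(list(bath), length(protocols)) else bath
  stopifnot(length(baths) == length(protocols))
  draw <- .draw_cohort(spec)
  cells <- lapply(seq_len(spec$n_cells), function(i)
    .cohort_cell(spec, draw, i))
  sweeps <- NULL
  if (keep_traces) {
    sweeps <- lapply(cells, function(cl)
      lapply(seq_along(protocols), function(k)
        simulate_sweeps(cl, protocols[[k]], baths[[k]], pipette)))
  }
  truth <- data.frame(cell_id = vapply(cells, `[[`, "", "cell_id"),
                      draw$present, capacitance_pF = draw$capacitance,
                      check.names = FALSE)
  for (f in .channel_families)
    truth[[paste0("gmax_", f)]] <- ifelse(draw$present[, f],
                                          draw$gmax[, f], 0)
  list(cells = cells, sweeps = sweeps, truth = truth, spec = spec)
}

#' Simulate and classify a cohort without retaining traces
#'
#' Streams through the cohort defined by `spec`: each cell is simulated under
#' the given protocols, classified with [classify_cell()], and its traces are
#' discarded. Template designs are precomputed once per protocol set, so the
#' per-cell cost is one simulation plus one least-squares projection.
#'
#' @inheritParams generate_population
#' @param criteria A [classification_criteria()].
#' @return A list with `results` (data.frame: per family, truth `true_*` and
#'   detection `det_*` flags per cell) and `incidence` (per-family detected
#'   counts, totals and integer percentages via [incidence()]).
#' @export
cohort_study <- function(spec, protocols, bath, pipette = pipette_preset(),
                         criteria = classification_criteria()) {
  stopifnot(inherits(spec, "population_spec"))
  if (inherits(protocols, "voltage_protocol")) protocols <- list(protocols)
  baths <- if (inherits(bath, "ionic_solution"))
    rep(list(bath), length(protocols)) else bath
  stopifnot(length(baths) == length(protocols))
  draw <- .draw_cohort(spec)
  design <- NULL
  fams <- .channel_families
  det <- matrix(FALSE, spec$n_cells, length(fams),
                dimnames = list(NULL, fams))
  for (i in seq_len(spec$n_cells)) {
    cl <- .cohort_cell(spec, draw, i)
    ss <- lapply(seq_along(protocols), function(k)
      simulate_sweeps(cl, protocols[[k]], baths[[k]], pipette))
    if (is.null(design) && criteria$method == "template")
      design <- template_design(ss, criteria, pipette)
    res <- classify_cell(ss, criteria, pipette = pipette, design = design)
    det[i, ] <- fams %in% res$labels
  }
  results <- data.frame(cell_id = sprintf("cell%04d", seq_len(spec$n_cells)))
  for (f in fams) {
    results[[paste0("true_", f)]] <- draw$present[, f]
    results[[paste0("det_", f)]] <- det[, f]
  }
  inc <- do.call(rbind, lapply(fams, function(f) {
    rec <- incidence(sum(det[, f]), spec$n_cells)
    data.frame(family = f, detected = rec$detected, total = rec$total,
               percent = rec$percent,
               true_present = sum(draw$present[, f]))
  }))
  list(results = results, incidence = inc)
}
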