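#' Cohort-level summary report
#'
#' Assembles the standard cohort tables from per-cell detection results:
#' incidence per channel family, amplitude mean +/- SEM at the reference
#' potentials, and (optionally) a pharmacology table of percent changes with
#' Mann-Whitney p-values. Deterministic given its inputs; an empty cohort
#' yields empty tables.
#'
#' @param detections List of `detection_result` objects (see
#'   [classify_cell()]).
#' @param comparisons Optional list of pharmacology comparisons; each element
#'   a list with `name`, `control` (vector of control currents, pA) and
#'   `test` (vector of currents under the intervention, pA). Percent change
#'   is computed from the group means; the p-value from
#'   [mann_whitney_u()] on the raw currents.
#' @param ivs Optional list of [iv_curve()]s, averaged per distinct measure
#'   into summary curves.
#' @return List of data.frames: `incidence`, `amplitudes`, `pharmacology`,
#'   plus `iv_summary` (list of averaged [iv_curve()]s).
#' @export
cohort_report <- function(detections = list(), comparisons = list(),
                          ivs = list()) {
  fams <- .channel_families
  total <- length(detections)
  inc <- do.call(rbind, lapply(fams, function(f) {
    k <- sum(vapply(detections, function(d) f %in% d$labels, TRUE))
    pct <- if (total > 0) incidence(k, total)$percent else NA_integer_
    data.frame(family = f, detected = k, total = total, percent = pct)
  }))
  amp <- do.call(rbind, lapply(fams, function(f) {
    vals <- unlist(lapply(detections, function(d)
      if (f %in% d$labels) d$amplitude_at_reference_pA[[f]] else NULL))
    if (length(vals) == 0)
      return(data.frame(family = f, reference_mV = NA_real_,
                        mean_pA = NA_real_, sem_pA = NA_real_, n = 0L))
    ref <- as.numeric(names(vals)[1])
    ms <- suppressWarnings(mean_sem(unname(vals)))
    data.frame(family = f, reference_mV = ref, mean_pA = ms$mean,
               sem_pA = ms$sem, n = ms$n)
  }))
  pharm <- NULL
  if (length(comparisons)) {
    pharm <- do.call(rbind, lapply(comparisons, function(cmp) {
      pc <- percent_change(mean(cmp$control), mean(cmp$test))
      mw <- mann_whitney_u(cmp$control, cmp$test,
                           group_a = "control", group_b = cmp$name)
      data.frame(comparison = cmp$name, n_control = length(cmp$control),
                 n_test = length(cmp$test), percent_change = pc,
                 u_statistic = mw$u_statistic, p_value = mw$p_value,
                 significant = mw$significant)
    }))
  } else {
    pharm <- data.frame(comparison = character(0), n_control = integer(0),
                        n_test = integer(0), percent_change = numeric(0),
                        u_statistic = numeric(0), p_value = numeric(0),
                        significant = logical(0))
  }
  iv_summary <- list()
  if (length(ivs)) {
    measures <- unique(vapply(ivs, `[[`, "", "measure"))
    iv_summary <- lapply(stats::setNames(nm = measures), function(m)
      average_ivs(Filter(function(x) x$measure == m, ivs)))
  }
  list(incidence = inc, amplitudes = amp, pharmacology = pharm,
       iv_summary = iv_summary)
}

#' Write a cohort report as CSV tables plus a markdown summary
#'
#' @param report A list from [cohort_report()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("incidence", "amplitudes", "pharmacology")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  md <- file.path(dir, "summary.md")
  lines <- c("# Cohort summary", "", "## Incidence", "",
             utils::capture.output(print(report$incidence)),
             "", "## Amplitudes at reference potentials", "",
             utils::capture.output(print(report$amplitudes)),
             "", "## Pharmacology", "",
             utils::capture.output(print(report$pharmacology)))
  writeLines(lines, md)
  invisible(c(paths, md))
}
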