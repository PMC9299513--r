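.protocol_to_list <- function(p)
  Filter(Negate(is.null), unclass(p))

.protocol_from_list <- function(x) do.call(voltage_protocol, x)

.solution_to_list <- function(s)
  list(name = s$name, concentrations_mM = as.list(s$concentrations_mM),
       temperature_K = s$temperature_K, ljp_mV = s$ljp_mV)

.solution_from_list <- function(x)
  ionic_solution(x$name, unlist(x$concentrations_mM), x$temperature_K,
                 x$ljp_mV)

#' Write a cohort of sweep sets as a portable trace bundle
#'
#' Serializes recordings to a documented plain-text bundle: one
#' `metadata.json` describing every trace file (cell id, protocol, bath,
#' potential convention) and one CSV per cell and protocol with a `time_ms`
#' column plus one current column per sweep, labelled by command potential
#' (`sweep_-45` etc., pA). Ground-truth labels, when given, go to a separate
#' `labels.csv` sidecar so blinded analysis is possible.
#'
#' @param sweepsets Either a list of [sweep_set()]s or a list of such lists
#'   (one inner list per cell).
#' @param dir Output directory (created if missing).
#' @param labels Optional data.frame of ground-truth labels (e.g. the
#'   `truth` element of [generate_population()]).
#' @return Invisibly, `dir`.
#' @export
write_sweep_bundle <- function(sweepsets, dir, labels = NULL) {
  if (length(sweepsets) && inherits(sweepsets[[1]], "sweep_set"))
    sweepsets <- list(sweepsets)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (cell in sweepsets) {
    for (s in cell) {
      fname <- sprintf("traces/%s_%s.csv", s$cell_id,
                       paste0("p", length(entries) + 1))
      df <- data.frame(time_ms = s$time_ms, s$sweeps, check.names = FALSE)
      names(df) <- c("time_ms",
                     paste0("sweep_", s$command_potentials_mV))
      utils::write.csv(df, file.path(dir, fname), row.names = FALSE)
      entries[[length(entries) + 1]] <- list(
        cell_id = s$cell_id, file = fname,
        command_potentials_mV = s$command_potentials_mV,
        ljp_applied = s$ljp_applied,
        protocol = .protocol_to_list(s$protocol),
        bath = .solution_to_list(s$bath))
    }
  }
  jsonlite::write_json(list(format = "rpeclamp-bundle-1", traces = entries),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(labels))
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trace bundle written by [write_sweep_bundle()]
#'
#' @param dir Bundle directory.
#' @return List per cell of [sweep_set()]s (named by cell id).
#' @export
read_sweep_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(meta$format, "rpeclamp-bundle-1"))
    stop("not an rpeclamp trace bundle")
  out <- list()
  for (e in meta$traces) {
    df <- utils::read.csv(file.path(dir, e$file), check.names = FALSE)
    s <- sweep_set(df$time_ms, as.matrix(df[-1]),
                   unlist(e$command_potentials_mV),
                   .protocol_from_list(e$protocol),
                   .solution_from_list(e$bath),
                   cell_id = e$cell_id, ljp_applied = isTRUE(e$ljp_applied))
    out[[e$cell_id]] <- c(out[[e$cell_id]], list(s))
  }
  out
}

#' Read a solutions/protocols configuration file
#'
#' Parses a YAML (or JSON) configuration with optional `solutions:` and
#' `protocols:` sections into [ionic_solution()] and [voltage_protocol()]
#' objects. See `system.file("extdata", "default-config.yaml",
#' package = "rpeclamp")` for the documented schema carrying the standard
#' presets.
#'
#' @param path Configuration file path.
#' @return List with elements `solutions` and `protocols` (named lists).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    solutions = lapply(cfg$solutions %||% list(), .solution_from_list),
    protocols = lapply(cfg$protocols %||% list(), .protocol_from_list))
}
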