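#' Load a run configuration from a YAML file
#'
#' Reads a structured text configuration with sections \code{topology},
#' \code{neuron_E}, \code{neuron_I}, \code{synapse}, \code{background},
#' \code{feedforward} and \code{engine} (integration/protocol settings),
#' validates every field, applies defaults for omitted fields and reports
#' which fields were defaulted.  Schema violations are reported with their
#' field path.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the defaulted-fields message.
#' @return A validated [run_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  builders <- list(
    topology = topology_config, neuron_E = neuron_params,
    neuron_I = neuron_params, synapse = synapse_params,
    background = background_params, feedforward = feedforward_params)
  known <- c(names(builders), "engine")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaulted <- character(0)
  build <- function(section) {
    fun <- builders[[section]]
    given <- raw[[section]]
    if (is.null(given)) given <- list()
    formal_names <- setdiff(names(formals(fun)), "...")
    extra <- setdiff(names(given), formal_names)
    if (length(extra))
      stop(sprintf("unknown field(s) in %s: %s", section,
                   paste0(section, ".", extra, collapse = ", ")),
           call. = FALSE)
    if (section %in% c("neuron_E", "neuron_I"))
      given$population <- sub("neuron_", "", section)
    miss <- setdiff(formal_names, c(names(given), "population"))
    defaulted <<- c(defaulted, paste0(section, ".", miss))
    tryCatch(do.call(fun, given),
             error = function(e)
               stop(sprintf("invalid %s section: %s", section,
                            conditionMessage(e)), call. = FALSE))
  }
  parts <- lapply(setNames(names(builders), names(builders)), build)
  eng <- raw$engine
  if (is.null(eng)) eng <- list()
  eng_formals <- c("dt", "t_transient", "t_measure", "orientations",
                   "contrast", "n_trials", "seed", "kinetics")
  extra <- setdiff(names(eng), eng_formals)
  if (length(extra))
    stop("unknown field(s) in engine: ",
         paste0("engine.", extra, collapse = ", "), call. = FALSE)
  defaulted <- c(defaulted,
                 paste0("engine.", setdiff(eng_formals, names(eng))))
  cfg <- tryCatch(
    do.call(run_config, c(parts, eng)),
    error = function(e)
      stop("invalid engine section: ", conditionMessage(e), call. = FALSE))
  if (!quiet && length(defaulted))
    message("defaults applied for: ", paste(defaulted, collapse = ", "))
  cfg
}

#' Save a run configuration to YAML
#'
#' Writes all sections of a [run_config()] so that
#' \code{load_config(save_config(cfg, path))} round-trips.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    x <- unclass(x)
    x$population <- NULL
    x
  }
  out <- list(
    topology = unclass(config$topology),
    neuron_E = strip(config$neuron_E),
    neuron_I = strip(config$neuron_I),
    synapse = unclass(config$synapse),
    background = unclass(config$background),
    feedforward = unclass(config$feedforward),
    engine = config[c("dt", "t_transient", "t_measure", "orientations",
                      "contrast", "n_trials", "seed", "kinetics")])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write spikes as an event table
#'
#' Serializes a [spike_data()] object to a CSV event table with columns
#' \code{trial}, \code{neuron_id} (0-based), \code{population},
#' \code{time_ms} (fixed 0.01 ms precision), plus a JSON sidecar
#' (\code{<path>.meta.json}) carrying the trial metadata and an MD5
#' checksum of the table.  A \code{.gz} extension compresses the table.
#'
#' @param spikes A [spike_data()] object.
#' @param path Output path (\code{.csv} or \code{.csv.gz}).
#' @param trial Trial index stored in the table.
#' @return \code{path}, invisibly.
#' @export
write_spikes <- function(spikes, path, trial = 1L) {
  stopifnot(inherits(spikes, "spike_data"))
  n_sp <- vapply(spikes$times, length, 1L)
  tab <- data.table::data.table(
    trial = trial,
    neuron_id = rep.int(seq_along(spikes$times) - 1L, n_sp),
    population = rep.int(spikes$population, n_sp),
    time_ms = sprintf("%.2f", unlist(spikes$times)))
  data.table::fwrite(tab, path)
  meta <- list(n_neurons = length(spikes$times),
               population = spikes$population,
               duration = spikes$duration, theta = spikes$theta,
               seed = spikes$seed,
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read spikes from an event table
#'
#' Reads a table written by [write_spikes()], verifying the sidecar
#' checksum when present.
#'
#' @param path Path to the CSV event table.
#' @return A [spike_data()] object.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path, call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(path)), meta$md5))
    stop("checksum mismatch: spike table is corrupt: ", path, call. = FALSE)
  tab <- data.table::fread(path, colClasses = list(
    integer = c("trial", "neuron_id"), character = "population",
    numeric = "time_ms"))
  times <- rep(list(numeric(0)), meta$n_neurons)
  if (nrow(tab)) {
    by_neuron <- split(tab$time_ms, factor(tab$neuron_id,
                                           levels = 0:(meta$n_neurons - 1)))
    times <- lapply(unname(by_neuron), sort)
  }
  spike_data(times = times, population = meta$population,
             duration = meta$duration, theta = meta$theta, seed = meta$seed)
}

#' Write connectivity as sparse coordinate lists
#'
#' One CSV per block (\code{EE.csv}, \code{EI.csv}, \code{IE.csv},
#' \code{II.csv}; columns \code{source_index}, \code{target_index},
#' 0-based, source = presynaptic) plus a \code{topology.json} sidecar with
#' the generating configuration.
#'
#' @param C A \code{"connectivity"} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_connectivity <- function(C, dir) {
  stopifnot(inherits(C, "connectivity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in c("EE", "EI", "IE", "II")) {
    M <- C[[b]]
    tab <- data.table::data.table(
      source_index = rep.int(seq_len(ncol(M)), diff(M@p)) - 1L,
      target_index = M@i)
    data.table::fwrite(tab, file.path(dir, paste0(b, ".csv")))
  }
  jsonlite::write_json(unclass(C$config), file.path(dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read connectivity written by [write_connectivity()]
#'
#' @param dir Directory containing the block CSVs and sidecar.
#' @return A \code{"connectivity"} object.
#' @export
read_connectivity <- function(dir) {
  side <- file.path(dir, "topology.json")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
  cfg <- do.call(topology_config, cfg)
  dims <- list(EE = c(cfg$N_E, cfg$N_E), EI = c(cfg$N_E, cfg$N_I),
               IE = c(cfg$N_I, cfg$N_E), II = c(cfg$N_I, cfg$N_I))
  blocks <- lapply(names(dims), function(b) {
    tab <- data.table::fread(file.path(dir, paste0(b, ".csv")))
    Matrix::sparseMatrix(i = tab$target_index + 1L,
                         j = tab$source_index + 1L,
                         dims = dims[[b]], repr = "C")
  })
  names(blocks) <- names(dims)
  structure(c(blocks, list(config = cfg)), class = "connectivity")
}
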