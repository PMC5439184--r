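#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON) file whose keys mirror the
#' \code{\link{network_config}}, \code{\link{neuron_params}} and
#' \code{\link{plasticity_params}} field names under the sections
#' \code{network}, \code{neuron} and \code{plasticity}. Missing fields are
#' filled with the model defaults; unknown keys and out-of-range values
#' are errors.
#'
#' @param path configuration file
#' @return list with validated \code{network}, \code{neuron} and
#'   \code{plasticity} components
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("network", "neuron", "plasticity"))
  if (length(unknown)) stop("unknown config section(s): ",
                            paste(unknown, collapse = ", "))
  build <- function(fun, args, what) {
    ok <- names(formals(fun))
    bad <- setdiff(names(args), ok)
    if (length(bad)) stop("unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  net <- build(network_config, raw$network %||% list(), "network")
  neu <- build(neuron_params, raw$neuron %||% list(), "neuron")
  pl_args <- raw$plasticity %||% list()
  # round-tripped configs store trace_mode in engine form (0/1)
  if (is.numeric(pl_args$trace_mode))
    pl_args$trace_mode <- c("restart", "sum")[pl_args$trace_mode + 1]
  pl <- do.call(plasticity_params, pl_args)
  list(network = net, neuron = neu, plasticity = pl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration to YAML
#' @param config list as returned by \code{\link{load_config}}
#' @param path output file
#' @return invisibly, the path
#' @export
save_config <- function(config, path) {
  strip <- function(x) { x <- unclass(x); x[!vapply(x, is.null, TRUE)] }
  yaml::write_yaml(list(network = strip(config$network),
                        neuron = strip(config$neuron),
                        plasticity = strip(config$plasticity)), path)
  invisible(path)
}

#' Save simulation state to a single-file container
#'
#' Serializes a network together with optional weight/calcium state and
#' spike records into one container file (RDS) with a format version tag,
#' giving a bit-faithful round-trip.
#'
#' @param network \code{lsm_network}
#' @param path output file
#' @param weights,calcium optional per-synapse state vectors
#' @param records optional list of \code{spike_record}s
#' @return invisibly, the path
#' @export
save_state <- function(network, path, weights = NULL, calcium = NULL,
                       records = NULL) {
  if (!is.null(weights) && length(weights) != nrow(network$synapses))
    stop("weights do not match the synapse table")
  obj <- list(format = "famlsm-state", version = 1L,
              network = network, weights = weights, calcium = calcium,
              records = records)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Load a state container
#'
#' @param path container file written by \code{\link{save_state}}
#' @param expect_dims optional grid dims; a mismatch is an explicit error
#' @return list with \code{network}, \code{weights}, \code{calcium},
#'   \code{records}
#' @export
load_state <- function(path, expect_dims = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt state container: ", conditionMessage(e)))
  if (!identical(obj$format, "famlsm-state"))
    stop("not a famlsm state container")
  if (!identical(obj$version, 1L))
    stop("unsupported container version: ", obj$version)
  if (!is.null(expect_dims) &&
      !all(obj$network$config$dims == as.integer(expect_dims)))
    stop(sprintf("container network shape %s does not match expected %s",
                 paste(obj$network$config$dims, collapse = "x"),
                 paste(expect_dims, collapse = "x")))
  obj[c("network", "weights", "calcium", "records")]
}

#' Export the synapse table as CSV
#' @param network \code{lsm_network}
#' @param path output file
#' @param weights optional weights overriding the stored ones
#' @return invisibly, the path
#' @export
export_edges <- function(network, path, weights = NULL) {
  tab <- network$synapses
  if (!is.null(weights)) tab$weight <- weights
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, all RNG stream seeds, a code
#' version tag, timestamps, and the output file inventory of a run
#' directory as JSON, so the run can be regenerated from the manifest
#' alone.
#'
#' @param dir run directory
#' @param config configuration list
#' @param master_seed master seed of the run
#' @param streams names of the RNG streams used
#' @return invisibly, the manifest path
#' @export
write_manifest <- function(dir, config, master_seed,
                           streams = c("grid", "connect", "weights", "input",
                                       "dynamics", "stimulus", "resample")) {
  seeds <- stats::setNames(
    lapply(streams, function(s) derive_seed(master_seed, s)), streams)
  plain <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), plain))
    if (is.numeric(x) && any(is.infinite(x)))
      return(ifelse(is.infinite(x), "Inf", as.character(x)))
    x
  }
  man <- list(package_version = as.character(utils::packageVersion("famlsm")),
              created = format(Sys.time(), tz = "UTC"),
              master_seed = master_seed, stream_seeds = seeds,
              config = plain(config),
              files = setdiff(list.files(dir), "manifest.json"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
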