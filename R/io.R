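#' Load a run configuration from a YAML file
#'
#' Reads a structured config with any subset of the simulation parameters
#' (defaults are the reference values, see [sim_params()]) plus the batch
#' controls `n_runs`, `master_seed`, `observation_budget`, the output
#' directory `out_dir`, and `quiet`. Unknown keys are rejected by name, as
#' are out-of-range parameter values.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A list with `params` (a [sim_params()] object), `n_runs`,
#'   `master_seed`, `observation_budget`, `out_dir`, `quiet`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("malformed config file: ", path, call. = FALSE)
  param_keys <- names(formals(sim_params))
  batch_keys <- c("n_runs", "master_seed", "observation_budget", "out_dir",
                  "quiet")
  unknown <- setdiff(names(raw), c(param_keys, batch_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(sim_params, raw[intersect(names(raw), param_keys)])
  get_or <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  n_runs <- get_or("n_runs", 1L)
  if (!is.numeric(n_runs) || n_runs < 1) {
    stop("parameter 'n_runs' must be >= 1", call. = FALSE)
  }
  list(
    params = params,
    n_runs = as.integer(n_runs),
    master_seed = as.integer(get_or("master_seed", 1L)),
    observation_budget = raw[["observation_budget"]],
    out_dir = get_or("out_dir", "."),
    quiet = isTRUE(raw[["quiet"]])
  )
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: serializes a config list so that a
#' write/load round trip reproduces it.
#'
#' @param config A list as returned by [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(unclass(config$params),
            list(n_runs = config$n_runs, master_seed = config$master_seed,
                 out_dir = config$out_dir, quiet = config$quiet))
  if (!is.null(config$observation_budget)) {
    flat$observation_budget <- config$observation_budget
  }
  yaml::write_yaml(flat, path)
  invisible(path)
}

tsv_write <- function(df, path) {
  df <- df[, setdiff(names(df), "founder_phenotypes"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

tsv_read <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialize run or batch outputs to TSV + JSON
#'
#' Writes `generations.tsv` (one row per generation record), `events.tsv`
#' (one row per colonization event; the in-memory founder-phenotype list
#' column is dropped), optional binned-surface tables
#' (`surface_<name>.tsv`), and `summary.json` with termination/batch
#' metadata. Columns are written in a fixed order with '.' as the decimal
#' separator, so outputs are byte-identical across re-runs with the same
#' seed and config.
#'
#' @param x An `ecofit_run` or `ecofit_batch`.
#' @param out_dir Output directory, created if needed.
#' @param surfaces Optional named list of surface data.frames from
#'   [success_curve()] or [phase_diagram()].
#' @return Character vector of the paths written, invisibly.
#' @export
write_tables <- function(x, out_dir, surfaces = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tsv_write(x$records, file.path(out_dir, "generations.tsv")),
    tsv_write(x$events, file.path(out_dir, "events.tsv"))
  )
  for (nm in names(surfaces)) {
    paths <- c(paths,
               tsv_write(surfaces[[nm]],
                         file.path(out_dir, paste0("surface_", nm, ".tsv"))))
  }
  summary <- if (inherits(x, "ecofit_run")) {
    list(type = "run", termination = x$termination,
         final_generation = x$final_generation, n_events = nrow(x$events),
         seed = x$seed, params = unclass(x$params))
  } else {
    list(type = "batch", n_runs = x$n_runs,
         n_records = nrow(x$records), n_events = nrow(x$events),
         n_post_burn_in = x$n_post_burn_in, seeds = x$seeds,
         params = unclass(x$params))
  }
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}

#' Read back tables written by [write_tables()]
#'
#' @param out_dir Directory holding `generations.tsv` and `events.tsv`.
#' @return A list with `records` and `events` data.frames.
#' @export
read_tables <- function(out_dir) {
  list(
    records = tsv_read(file.path(out_dir, "generations.tsv")),
    events = tsv_read(file.path(out_dir, "events.tsv"))
  )
}
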