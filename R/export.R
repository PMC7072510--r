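#' Write result tables as CSV
#'
#' Thin wrappers emitting the standard UTF-8 CSVs with a header row. Output
#' is deterministic: identical inputs produce byte-identical files.
#'
#' @param x Tibble to write (well table, dose-response, fold changes, spot
#'   or nucleus object tables, stats tables).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of outputs: package version, a hash of the
#' configuration, input files, parameter values, and per-stage object
#' counts. Timestamps are included for the record but everything else is a
#' pure function of the inputs, so two runs over identical data differ only
#' in the timestamp field.
#'
#' @param config The list returned by [read_config()] (or any serialisable
#'   configuration object).
#' @param inputs Character vector of input file paths.
#' @param counts Named list/vector of per-stage object counts.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs, counts, path) {
  manifest <- list(
    tool = "mnquant",
    version = as.character(utils::packageVersion("mnquant")),
    config_hash = rlang::hash(config),
    inputs = as.character(inputs),
    parameters = config,
    object_counts = as.list(counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
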