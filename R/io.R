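# Tab-separated I/O for the package's tables, plus the run manifest.
# TSV (not CSV) avoids locale decimal issues; UTF-8; header row mandatory.

#' Write / read a census time course as TSV
#'
#' Columns `replicate`, `time_h`, `population`, `count`. A written table
#' reads back field-for-field equal.
#'
#' @param tc A `gc_timecourse` (or any tibble with those columns).
#' @param path File path.
#' @export
write_timecourse <- function(tc, path) {
  readr::write_tsv(tc[, c("replicate", "time_h", "population", "count")],
                   path)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    replicate = "i", time_h = "d", population = "c", count = "d"))
  class(out) <- c("gc_timecourse", class(out))
  out
}

#' Write / read aggregated curves (population, mean, sd) as TSV
#'
#' @param agg Output of [aggregate_timecourse()].
#' @param path File path.
#' @export
write_aggregate <- function(agg, path) {
  readr::write_tsv(agg, path)
  invisible(path)
}

#' @rdname write_aggregate
#' @export
read_aggregate <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    time_h = "d", population = "c", mean = "d", sd = "d", n = "i"))
}

#' Write / read a CTV composition table as TSV
#'
#' Columns `compartment`, `subpop`, `percent` (plus any extra columns
#' present, e.g. `n`).
#'
#' @param composition Output of [ctv_composition()].
#' @param path File path.
#' @export
write_composition <- function(composition, path) {
  readr::write_tsv(composition, path)
  invisible(path)
}

#' @rdname write_composition
#' @export
read_composition <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    compartment = "c", subpop = "c", .default = "d"))
}

#' Run manifest
#'
#' Captures everything needed to re-run an analysis: the resolved
#' configuration and topology, the seed, the package version, the start
#' time, and md5 checksums of the produced files. Written as YAML next to
#' the outputs.
#'
#' @param path Manifest file path.
#' @param config A [gc_config()].
#' @param topology A [gc_topology()].
#' @param seed Integer seed of the run.
#' @param files Character vector of output files to checksum.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, topology, seed, files = character()) {
  cfg <- unclass(config)
  cfg$affinity <- unclass(cfg$affinity)
  if (!is.null(cfg$pulses)) cfg$pulses <- as.list(cfg$pulses)
  manifest <- list(
    package = "gcmyc",
    version = as.character(utils::packageVersion("gcmyc")),
    started = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    topology = list(name = topology$name,
                    params = as.list(stats::setNames(
                      topology$params$hours, topology$params$name))),
    config = cfg,
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(f))))
  )
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
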