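#' Write a JSON run manifest
#'
#' Every pipeline stage records its inputs, seed, thresholds, package and
#' R versions, counts, and warnings to a JSON manifest so runs are
#' auditable and reproducible.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param inputs Named list/character of input paths.
#' @param seed Integer seed used, or \code{NA}.
#' @param params Named list of thresholds and parameters.
#' @param counts Named list of record counts.
#' @param warnings Character vector of warnings.
#' @return Invisibly, \code{path}.
#' @export
writeRunManifest <- function(path, stage, inputs = list(), seed = NA,
                             params = list(), counts = list(),
                             warnings = character(0)) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = as.character(utils::packageVersion("pescreen")),
    r_version = R.version.string,
    inputs = inputs,
    seed = seed,
    params = params,
    counts = counts,
    warnings = warnings
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Default analysis thresholds
#'
#' The thresholds used throughout the pipeline: minimum deep-sequencing
#' read count (100), PE2-efficiency stratification threshold (1\%),
#' fold-change pseudocount (0.1 percentage points), and the substitution
#' analysis window (offsets -10 to +25 from the nick site). All are
#' overridable per call and echoed into run manifests.
#'
#' @return Named list.
#' @export
defaultThresholds <- function() {
  list(
    min_reads = 100L,
    pe2_threshold = 1.0,
    pseudocount = 0.1,
    window = c(-10L, 25L)
  )
}
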