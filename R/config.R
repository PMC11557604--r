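#' Read an experiment configuration from YAML
#'
#' Missing fields are filled with the standard design defaults (n = 500,
#' benchmarks 10/30%, missingness sd 20, scenarios 20/40/60/80%, 1000
#' iterations, 75% threshold, 10,000 draws, 75-100% prediction range). An
#' empty file therefore yields the full default design. Field-level
#' validation errors are raised by [experiment_config()].
#'
#' @param path YAML file whose keys mirror the [experiment_config()]
#'   arguments.
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML
#'
#' @param cfg An [experiment_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate fixture files
#'
#' Runs the full invariant suite on a trauma-pool fixture (40 cases, pattern
#' sums matching declared counts, injured elements on declared bones) and a
#' bone-ESS fixture (all 14 bones, positive values), reporting per-file
#' status. Raises on the first violation unless `quiet_fail = TRUE`.
#'
#' @param pool_path,ess_path Fixture paths (defaults: shipped fixtures).
#' @param quiet_fail Return the error message instead of raising.
#' @return List with `pool_ok`, `ess_ok`, `errors` (character).
#' @export
validate_fixtures <- function(pool_path = default_fixture("pool"),
                              ess_path = default_fixture("ess"),
                              quiet_fail = FALSE) {
  schema <- cranial_schema()
  errors <- character()
  pool_ok <- tryCatch({read_trauma_pool(schema, pool_path); TRUE},
                      error = function(e) {
                        errors <<- c(errors, conditionMessage(e)); FALSE})
  ess_ok <- tryCatch({read_bone_ess(schema, ess_path); TRUE},
                     error = function(e) {
                       errors <<- c(errors, conditionMessage(e)); FALSE})
  if (!quiet_fail && length(errors))
    stop("fixture validation failed:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  list(pool_ok = pool_ok, ess_ok = ess_ok, errors = errors)
}

#' Build a run manifest for an experiment
#'
#' Collects everything needed to replay a run exactly: the full configuration
#' (master seed included), MD5 hashes of the fixture files actually used, the
#' package version and a timestamp, plus per-scenario GLM fallback and
#' failure counts when results are supplied.
#'
#' @param cfg An [experiment_config()].
#' @param experiment Optional `"trauma_experiment"` for the fallback counts.
#' @return List suitable for JSON serialization.
#' @export
run_manifest <- function(cfg, experiment = NULL) {
  pool_path <- if (is.null(cfg$pool_path)) default_fixture("pool") else cfg$pool_path
  ess_path <- if (is.null(cfg$ess_path)) default_fixture("ess") else cfg$ess_path
  man <- list(
    config = unclass(cfg),
    fixtures = list(
      pool = list(path = pool_path, md5 = unname(tools::md5sum(pool_path))),
      ess = list(path = ess_path, md5 = unname(tools::md5sum(ess_path)))),
    package_version = as.character(utils::packageVersion("traumasim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(experiment)) {
    man$glm_fallbacks <- as.list(experiment$summary$glm_fallbacks)
    man$glm_failures <- as.list(experiment$summary$glm_failures)
  }
  man
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()] list.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(manifest, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
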