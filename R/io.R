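#' Read a scenario configuration from YAML or JSON
#'
#' Reads a configuration file whose keys mirror the arguments of
#' [scenario_config()], applies defaults for absent keys, rejects unknown
#' keys, and validates every invariant. An empty file yields the full
#' default (null-effect) scenario.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  values <- switch(ext,
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    stop("unsupported config format `.", ext, "` (use YAML or JSON)",
         call. = FALSE)
  )
  if (is.null(values) || length(values) == 0L) return(scenario_config())
  if (!is.list(values)) stop("config must be a mapping of parameter: value",
                             call. = FALSE)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(values$covariate_prevalences)) {
    values$covariate_prevalences <- unlist(values$covariate_prevalences)
  }
  do.call(scenario_config, values)
}

#' Write a scenario configuration to YAML or JSON
#'
#' @param cfg a `scenario_config`.
#' @param path destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_scenario_config(cfg)
  values <- unclass(cfg)
  values$covariate_prevalences <- as.list(cfg$covariate_prevalences)
  values <- values[!vapply(values, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "json" = jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA),
    "yaml" = ,
    "yml" = yaml::write_yaml(values, path, precision = 15L),
    stop("unsupported config format `.", ext, "` (use YAML or JSON)",
         call. = FALSE)
  )
  invisible(path)
}

#' Derive per-replicate seeds from a master seed
#'
#' Replicate streams are split from the master seed by drawing a vector of
#' integer seeds under the master seed, so that replicate `r` can be
#' reproduced in isolation by regenerating the vector and seeding with its
#' `r`-th element.
#'
#' @param master_seed integer master seed.
#' @param reps number of replicates.
#' @return Integer vector of length `reps`.
#' @export
derive_rep_seeds <- function(master_seed, reps) {
  stopifnot(reps >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a run byte-for-byte: the full
#' configuration, the master seed, the seed-derivation rule and the package
#' version.
#'
#' @param cfg a `scenario_config`.
#' @param seed master seed used.
#' @param reps replicate count (if a Monte Carlo run).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(cfg, seed, reps = NULL) {
  structure(list(
    config = unclass(cfg),
    master_seed = seed,
    reps = reps,
    seed_rule = "set.seed(master); sample.int(.Machine$integer.max - 1L, reps)",
    package_version = as.character(utils::packageVersion("alsmams")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("alsmams run manifest\n")
  cat("  version:", x$package_version, "\n")
  cat("  master seed:", x$master_seed, "\n")
  if (!is.null(x$reps)) cat("  replicates:", x$reps, "\n")
  cat("  seed rule:", x$seed_rule, "\n")
  invisible(x)
}

#' Write the manifest as JSON
#' @param manifest a `run_manifest`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Deterministic CSV writer: always writes a header, never row names.
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write cohort tables to CSV
#'
#' Writes the long-format visit table (participant, arm, entry time,
#' covariates, visit month, ALSFRS-R score) and the survival table
#' (participant, time, event flag, arm, covariates).
#'
#' @param cohort a cohort as returned by [simulate_cohort()].
#' @param visits_path,survival_path destination CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, visits_path, survival_path) {
  p <- cohort$participants
  v <- cohort$visits
  long <- merge(
    v,
    p[, c("id", "arm", "entry_time", "riluzole", "niv_gastrostomy",
          "long_survivor")],
    by.x = "participant_id", by.y = "id", sort = FALSE
  )
  long <- long[order(long$participant_id, long$visit_month),
               c("participant_id", "arm", "entry_time", "riluzole",
                 "niv_gastrostomy", "long_survivor", "visit_month",
                 "alsfrs_r")]
  write_table_csv(long, visits_path)
  write_table_csv(cohort$survival, survival_path)
  invisible(c(visits_path, survival_path))
}
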