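# Run configuration (YAML/JSON), schedule declarations, CSV export and run
# manifests.

.config_defaults <- function() {
  list(
    seed = 0L,
    out_dir = "results",
    params = list(),
    schedule = list(kind = "pattern", mean = 37, amplitude = 3,
                    period = 24, warm_fraction = 0.5,
                    orientation = "normal"),
    population = list(n_cells = 200L, range_frac = 0.1, vary = NULL,
                      skip = 0L),
    individuals = list(n_subjects = 50L, cells_per_subject = 100L,
                       lower = 0.5, upper = 2),
    solver = list(rtol = 1e-6, atol = 1e-9, dt = 0.25, method = "adams"),
    metrics = list(burn_in_h = 480, window_h = 1200,
                   phase_reference = "warm")
  )
}

.schedule_keys <- c("kind", "mean", "amplitude", "period", "warm_fraction",
                    "orientation", "value", "spec", "pre_days",
                    "amplitude_normal", "amplitude_reversed", "first",
                    "rhythm_on_d", "rhythm_off_d")

# merge user values over defaults, collecting every unknown-key complaint
.merge_section <- function(defaults, user, section, errors) {
  if (is.null(user)) return(list(value = defaults, errors = errors))
  if (!is.list(user)) {
    return(list(value = defaults,
                errors = c(errors, sprintf("`%s` must be a mapping",
                                           section))))
  }
  if (section == "params") {
    # free-form parameter overrides; names are validated against the
    # canonical table afterwards
    return(list(value = user, errors = errors))
  }
  known <- if (section == "schedule") .schedule_keys else names(defaults)
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown key(s) in `%s`: %s", section,
                                paste(unknown, collapse = ", ")))
    user <- user[setdiff(names(user), unknown)]
  }
  defaults[names(user)] <- user
  list(value = defaults, errors = errors)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills defaults (nominal
#' parameters, the W12/C12 37 +/- 1.5 degC pattern, a 200-cell population,
#' seed 0) and validates. Every problem found is reported at once, and
#' unknown keys are rejected by name. An empty or absent configuration
#' yields the full default run.
#'
#' @param path Path to a YAML/JSON file, or `NULL`.
#' @param config A configuration list given directly (overrides `path`).
#' @return A validated `run_config` list.
#' @export
#' @examples
#' cfg <- load_config(config = list(params = list(khsf1 = 0)))
#' cfg$params$khsf1
load_config <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path)) {
      config <- list()
    } else {
      if (!file.exists(path)) {
        stop("config file not found: ", path, call. = FALSE)
      }
      config <- yaml::read_yaml(path)
      if (is.null(config)) config <- list()
    }
  }
  defaults <- .config_defaults()
  errors <- character(0)
  top_unknown <- setdiff(names(config), names(defaults))
  if (length(top_unknown)) {
    errors <- c(errors, paste0("unknown top-level key(s): ",
                               paste(top_unknown, collapse = ", ")))
  }
  out <- defaults
  for (sec in c("params", "schedule", "population", "individuals",
                "solver", "metrics")) {
    m <- .merge_section(defaults[[sec]], config[[sec]], sec, errors)
    out[[sec]] <- m$value
    errors <- m$errors
  }
  for (key in c("seed", "out_dir")) {
    if (!is.null(config[[key]])) out[[key]] <- config[[key]]
  }
  # parameter overrides: names against the canonical 41, values validated
  if (length(out$params)) {
    unknown <- setdiff(names(out$params), param_names())
    if (length(unknown)) {
      errors <- c(errors, paste0("unknown parameter(s): ",
                                 paste(unknown, collapse = ", ")))
    }
    for (nm in intersect(names(out$params), param_names())) {
      v <- out$params[[nm]]
      if (!is.numeric(v) || !is.finite(v) || v < 0) {
        errors <- c(errors,
                    sprintf("parameter `%s` must be a finite number >= 0",
                            nm))
      } else if (nm %in% c("n", "p", "q", "r") && v < 1) {
        errors <- c(errors,
                    sprintf("Hill exponent `%s` must be >= 1", nm))
      }
    }
  }
  sc <- out$schedule
  if (!sc$kind %in% c("pattern", "constant", "ass", "validation")) {
    errors <- c(errors, sprintf(
      "schedule kind must be pattern/constant/ass/validation, got `%s`",
      sc$kind))
  }
  if (identical(sc$kind, "ass") && is.null(sc$spec)) {
    errors <- c(errors, "schedule kind `ass` needs a `spec` (\"N-n1:n2\")")
  }
  if (!is.null(sc$amplitude) && sc$amplitude < 0) {
    errors <- c(errors, "schedule amplitude must be >= 0")
  }
  pp <- out$population
  if (pp$n_cells < 2) errors <- c(errors, "population n_cells must be >= 2")
  if (pp$range_frac < 0 || pp$range_frac >= 1) {
    errors <- c(errors, "population range_frac must be in [0, 1)")
  }
  if (out$solver$dt <= 0) errors <- c(errors, "solver dt must be > 0")
  if (length(errors)) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(out, class = "run_config")
}

#' Build the parameter set declared by a configuration
#'
#' @param config A `run_config`.
#' @return A one-row parameter tibble (nominal values plus overrides).
#' @export
config_params <- function(config) {
  do.call(clock_params, config$params)
}

#' Build the schedule declared by a configuration
#'
#' @param config A `run_config`.
#' @return A `temp_schedule`.
#' @export
config_schedule <- function(config) {
  sc <- config$schedule
  switch(sc$kind,
    constant = constant_schedule(sc$value %||% sc$mean %||% 37),
    pattern = pattern_schedule(temp_pattern(
      mean = sc$mean, amplitude = sc$amplitude, period = sc$period,
      warm_fraction = sc$warm_fraction, orientation = sc$orientation)),
    ass = ass_schedule(sc$spec,
      pre_days = sc$pre_days %||% 50, mean = sc$mean,
      amplitude_normal = sc$amplitude_normal %||% sc$amplitude,
      amplitude_reversed = sc$amplitude_reversed %||% sc$amplitude,
      first = sc$first %||% "reversed"),
    validation = validation_schedule(
      orientation = sc$orientation,
      rhythm_on_d = sc$rhythm_on_d %||% 10,
      rhythm_off_d = sc$rhythm_off_d %||% 65,
      mean = sc$mean, amplitude = sc$amplitude))
}

#' Write a trajectory or table as CSV
#'
#' Plain CSV with a mandatory header row; trajectories put `time_h` first.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# hash the canonical JSON form so YAML/JSON type jitter (int vs double)
# cannot break replay verification
.config_hash <- function(config) {
  digest::digest(as.character(jsonlite::toJSON(
    unclass(config), auto_unbox = TRUE, digits = NA, null = "null")),
    algo = "sha256", serialize = FALSE)
}

#' Write a run manifest
#'
#' Records the configuration (floats at full precision), its hash, the
#' seed, package version and the hashes of every output file, so a run can
#' be replayed and verified byte-for-byte.
#'
#' @param config A `run_config`.
#' @param seed Seed the run used.
#' @param outputs Character vector of output file paths.
#' @param path Manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, outputs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  man <- list(
    package = "thermoclock",
    version = as.character(utils::packageVersion("thermoclock")),
    seed = seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    outputs = lapply(outputs, function(f) {
      list(file = f, sha256 = digest::digest(file = f, algo = "sha256"))
    })
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Verify a run manifest
#'
#' Recomputes the configuration hash and every output file hash; any
#' mismatch (tampered config, regenerated outputs) is reported.
#'
#' @param path Manifest path.
#' @param base_dir Directory output paths are relative to.
#' @return `TRUE` invisibly if everything matches; otherwise an error
#'   naming the mismatches.
#' @export
verify_manifest <- function(path, base_dir = dirname(path)) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  problems <- character(0)
  cfg <- load_config(config = man$config)
  if (!identical(.config_hash(cfg), man$config_hash)) {
    problems <- c(problems, "config hash mismatch")
  }
  for (o in man$outputs) {
    f <- if (file.exists(o$file)) o$file else file.path(base_dir, o$file)
    if (!file.exists(f)) {
      problems <- c(problems, paste0("missing output: ", o$file))
    } else if (!identical(digest::digest(file = f, algo = "sha256"),
                          o$sha256)) {
      problems <- c(problems, paste0("hash mismatch: ", o$file))
    }
  }
  if (length(problems)) {
    stop("manifest verification failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}
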