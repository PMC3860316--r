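# Configuration and file I/O.
#
# Plain CSV throughout: trial logs and threshold tables are meant to be
# human-auditable and readable by external stats tools. Every file carries
# a comment header embedding the master seed, a config hash and the
# package version; existing files are never appended to — a numeric suffix
# versions new writes.

#' Default run configuration
#'
#' @return A named list with the full default configuration: the
#'   density/frames experiment, psychometric observer, 10 participants per
#'   group, high-density 8-frame stimulus defaults, and the experiment's
#'   staircase settings.
#' @export
default_run_config <- function() {
  list(
    experiment = "exp1",
    observer = "psychometric",
    n_per_group = 10,
    seed = 1,
    out_dir = ".",
    cohort = list(
      alpha_mean = NULL, # NULL = the selected experiment's calibration
      alpha_sd = NULL,
      beta = 3, lapse = 0.01, bias_left = 0.5),
    stimulus = list(preset = "exp1_high_density", n_frames = 8),
    staircase = list(
      start_coherence_pct = 50, n_reversals = 8,
      coherence_cap_pct = 100, coherence_floor_pct = 0.1,
      catch_coherence_pct = 1, catch_every = 5,
      discard_first_k = 0, max_trials = 400)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    keypath <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key: %s", keypath), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config key %s must be a mapping", keypath),
             call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$experiment %in% c("exp1", "exp2"),
            cfg$observer %in% c("psychometric", "mechanistic"),
            cfg$n_per_group >= 1)
  if (!is.null(cfg$stimulus$preset) &&
      !cfg$stimulus$preset %in% names(rdk_presets())) {
    stop(sprintf("unknown config key value: stimulus$preset = '%s'",
                 cfg$stimulus$preset), call. = FALSE)
  }
  sc <- cfg$staircase
  if (sc$start_coherence_pct <= 0 ||
      sc$start_coherence_pct > sc$coherence_cap_pct) {
    stop("config invariant violated: staircase$start_coherence_pct",
         call. = FALSE)
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Missing keys are filled from [default_run_config()]; unknown keys are
#' rejected with an error naming the offending key path.
#'
#' @param path Path to a YAML file (an empty file yields the full
#'   defaults).
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_run_config(merge_config(default_run_config(), user))
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(cfg) {
  # order-stable digest of the configuration via its serialised YAML
  txt <- yaml::as.yaml(cfg[order(names(cfg))])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

versioned_path <- function(dir, stem, ext = "csv") {
  path <- file.path(dir, sprintf("%s.%s", stem, ext))
  v <- 1L
  while (file.exists(path)) {
    v <- v + 1L
    path <- file.path(dir, sprintf("%s_v%d.%s", stem, v, ext))
  }
  path
}

write_csv_with_header <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rdksim %s", as.character(utils::packageVersion("rdksim"))),
    sprintf("# master_seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("# config_hash: %s", hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Write experiment results to disk
#'
#' Writes `thresholds.csv` (one row per participant x condition),
#' `summary.csv` (group x condition cells) and, when the result carries a
#' trial log, `trials.csv`. Files are never appended to: if a name exists,
#' a `_v2`, `_v3`, ... suffix is used. Each file starts with comment lines
#' recording the package version, master seed and config hash.
#'
#' @param result An `experiment_result`.
#' @param summary Optional [summarize_thresholds()] output (computed from
#'   `result` if omitted).
#' @param dir Output directory, created if missing.
#' @param seed The master seed to record in the headers.
#' @param config Optional configuration list to hash into the headers.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_results <- function(result, summary = NULL, dir = ".", seed = NULL,
                          config = default_run_config()) {
  stopifnot(inherits(result, "experiment_result") || is.data.frame(result))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(summary) && inherits(result, "experiment_result") &&
      nrow(result) > 0) {
    summary <- summarize_thresholds(result)
  }
  hash <- config_hash(config)
  paths <- c(thresholds = write_csv_with_header(
    as.data.frame(result), versioned_path(dir, "thresholds"), seed, hash))
  if (!is.null(summary)) {
    paths["summary"] <- write_csv_with_header(
      as.data.frame(summary$cells), versioned_path(dir, "summary"),
      seed, hash)
  }
  trials <- attr(result, "trials")
  if (!is.null(trials)) {
    paths["trials"] <- write_csv_with_header(
      as.data.frame(trials), versioned_path(dir, "trials"), seed, hash)
  }
  invisible(paths)
}

#' Read a results CSV written by [write_results()]
#'
#' Skips the comment header and restores column types, so that a written
#' `thresholds.csv` round-trips to the tabular content of the
#' `experiment_result` it came from.
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Run an experiment from a configuration
#'
#' The programmatic equivalent of the command-line interface: loads or
#' takes a configuration, runs the selected experiment and writes the
#' result files.
#'
#' @param config A `run_config` (from [load_config()]) or a plain list of
#'   overrides merged onto [default_run_config()].
#' @return Invisibly, a list with `result`, `summary`, and `paths`.
#' @export
run_from_config <- function(config = list()) {
  if (!inherits(config, "run_config")) {
    config <- validate_run_config(merge_config(default_run_config(), config))
  }
  cohort <- default_cohort(config$experiment,
                           n_per_group = config$n_per_group)
  if (!is.null(config$cohort$alpha_mean)) {
    cohort$alpha_mean <- unlist(config$cohort$alpha_mean)[c("control",
                                                            "dyslexia")]
  }
  if (!is.null(config$cohort$alpha_sd)) {
    cohort$alpha_sd <- unlist(config$cohort$alpha_sd)[c("control",
                                                        "dyslexia")]
  }
  cohort$beta <- config$cohort$beta
  cohort$lapse <- config$cohort$lapse
  cohort$bias_left <- config$cohort$bias_left
  runner <- if (config$experiment == "exp1") run_experiment1
            else run_experiment2
  result <- runner(cohort, seed = config$seed,
                   observer_model = config$observer)
  summary <- summarize_thresholds(result)
  paths <- write_results(result, summary, dir = config$out_dir,
                         seed = config$seed, config = config)
  invisible(list(result = result, summary = summary, paths = paths))
}
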