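#' Read and validate an experiment configuration
#'
#' Loads a YAML (`.yml`/`.yaml`) or JSON configuration describing the full
#' experiment -- conditions, staircase block, observer block, session block
#' and optional output paths -- validates it against the package's schema
#' (see `inst/extdata/config-schema.json` for the documented structure),
#' fills defaults, and returns a ready-to-run configuration object.
#'
#' @param path Path to the configuration file.
#' @return An object of class `"amdt_config"`.
#' @examples
#' cfg <- read_experiment_config(
#'   system.file("extdata", "example-config.yaml", package = "amtrack"))
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    stop_amtrack("config file not found: ", path, class = "amtrack_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_experiment_config(raw, dir = dirname(path))
}

#' @rdname read_experiment_config
#' @param config A raw configuration list.
#' @param dir Directory against which relative file references are resolved.
#' @export
validate_experiment_config <- function(config, dir = ".") {
  fail <- function(...) stop_amtrack("config: ", ..., class = "amtrack_config_error")
  if (!is.list(config)) fail("top level must be a mapping")

  conds <- config$conditions
  if (is.null(conds) || length(conds) == 0L) fail("'conditions' must be non-empty")
  if (is.data.frame(conds)) conds <- split(conds, seq_len(nrow(conds)))
  conditions <- lapply(conds, function(cc) {
    cc <- as.list(cc)
    if (is.null(cc$carrier_hz) || is.null(cc$mod_hz))
      fail("each condition needs 'carrier_hz' and 'mod_hz'")
    condition(cc$carrier_hz, cc$mod_hz)
  })

  st <- config$staircase %||% list()
  sess <- config$session %||% list()
  reps_per_position <- sess$reps_per_position %||% 12
  repetitions <- sess$repetitions %||% 3
  run_trials <- 3 * reps_per_position * repetitions
  staircase <- staircase_config(
    start_value = st$start_value %||% 6,
    step_sizes = as.numeric(st$step_sizes %||% c(1, 0.5)),
    change_points = as.numeric(st$change_points %||% 1),
    n_down = st$n_down %||% 3,
    schedule_mode = st$schedule_mode %||% "reversal",
    max_trials = st$max_trials %||% run_trials,
    max_reversals = st$max_reversals,
    min_value = st$min_value %||% -Inf,
    max_value = st$max_value %||% Inf)

  ob <- config$observer %||% list()
  observer <- psychometric_model(midpoint = ob$midpoint_db %||% -9,
                                 std = ob$std_db %||% 2,
                                 guess_rate = ob$guess_rate %||% 0)

  calibration <- NULL
  if (!is.null(config$calibration_file)) {
    cal_path <- config$calibration_file
    if (!file.exists(cal_path)) cal_path <- file.path(dir, config$calibration_file)
    if (!file.exists(cal_path)) fail("calibration file not found: ",
                                     config$calibration_file)
    calibration <- read_calibration_profile(cal_path)
  }

  structure(list(
    conditions = conditions,
    staircase = staircase,
    observer = observer,
    n_participants = sess$n_participants %||% 10,
    reps_per_position = reps_per_position,
    repetitions = repetitions,
    stim_duration_s = sess$stim_duration_s %||% 0.5,
    onsets_s = as.numeric(sess$onsets_s %||% c(0.5, 1.5, 2.5)),
    trial_period_s = sess$trial_period_s %||% 4,
    rate = sess$rate %||% 44100,
    base_seed = as.integer(sess$base_seed %||% 1),
    n_reversals = sess$n_reversals %||% 6,
    calibration = calibration), class = "amdt_config")
}

#' @export
print.amdt_config <- function(x, ...) {
  cat(sprintf("<amdt_config: %d conditions, %d participants, %d x %d trials/condition, base seed %d>\n",
              length(x$conditions), x$n_participants,
              x$repetitions, 3 * x$reps_per_position, x$base_seed))
  invisible(x)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)                      # scratch file only, for hashing
  unname(tools::md5sum(tmp))
}
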