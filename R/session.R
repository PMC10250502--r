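#' Experimental condition
#'
#' A carrier/modulation frequency pair for the 3-AFC amplitude-modulation
#' detection test.
#'
#' @param carrier_hz Carrier frequency in Hz (> 0).
#' @param mod_hz Modulation frequency in Hz (> 0).
#' @export
condition <- function(carrier_hz, mod_hz) {
  if (!is.finite(carrier_hz) || carrier_hz <= 0 ||
      !is.finite(mod_hz) || mod_hz <= 0)
    stop_amtrack("condition frequencies must be positive",
                 class = "amtrack_config_error")
  structure(list(carrier_hz = carrier_hz, mod_hz = mod_hz), class = "amdt_condition")
}

#' The four default test conditions
#'
#' Carrier 400/1000 Hz crossed with modulation 5/10 Hz.
#' @export
default_conditions <- function() {
  list(condition(400, 5), condition(1000, 5),
       condition(400, 10), condition(1000, 10))
}

#' Build a balanced, shuffled trial plan
#'
#' For each condition, a shuffled sequence of `3 * reps_per_position` target
#' positions in which each of the three intervals occurs exactly
#' `reps_per_position` times; the condition order itself is also shuffled.
#' Uses R's random stream (seed with [set.seed()]).
#'
#' @param conditions Non-empty list of [condition()] objects.
#' @param reps_per_position Occurrences of each target position per condition
#'   (12 gives 36 trials per condition).
#' @return A list with one element per condition (in shuffled play order),
#'   each `list(condition =, positions =)`.
#' @export
build_condition_plan <- function(conditions, reps_per_position = 12) {
  if (length(conditions) == 0L)
    stop_amtrack("need at least one condition", class = "amtrack_config_error")
  if (reps_per_position < 1 || reps_per_position != round(reps_per_position))
    stop_amtrack("'reps_per_position' must be a positive integer",
                 class = "amtrack_config_error")
  ord <- sample.int(length(conditions))
  lapply(conditions[ord], function(cond) {
    stopifnot(inherits(cond, "amdt_condition"))
    list(condition = cond,
         positions = sample(rep(1:3, reps_per_position)))
  })
}

#' Stimulus onsets within a trial
#'
#' The three intervals start 0.5, 1.5 and 2.5 s after trial start (a 1 s
#' inter-onset grid).
#'
#' @param onsets_s Onset times in seconds from trial start.
#' @return A data frame: `stimulus` (1:3), `onset_s`.
#' @export
trial_timeline <- function(onsets_s = c(0.5, 1.5, 2.5)) {
  data.frame(stimulus = seq_along(onsets_s), onset_s = onsets_s)
}

#' Append a marker to an event stream
#'
#' @param stream A data frame with columns `label`, `timestamp_s` (possibly
#'   zero rows), as created by `marker_stream()`.
#' @param label Marker label.
#' @param timestamp_s Timestamp in seconds; must not precede the last marker.
#' @return The extended stream.
#' @export
emit_marker <- function(stream, label, timestamp_s) {
  if (nrow(stream) > 0 && timestamp_s < stream$timestamp_s[nrow(stream)])
    stop_amtrack("non-monotonic marker timestamp: ", timestamp_s, " < ",
                 stream$timestamp_s[nrow(stream)], class = "amtrack_clock_error")
  rbind(stream, data.frame(label = label, timestamp_s = timestamp_s))
}

#' @rdname emit_marker
#' @export
marker_stream <- function() {
  data.frame(label = character(0), timestamp_s = numeric(0))
}

#' Run one 3-AFC trial against the simulated observer
#'
#' Presents three intervals on the trial timeline -- two unmodulated tones
#' and, at `target_position`, an AM tone at the staircase's current depth --
#' draws the observer's answer from the psychometric model, and updates the
#' staircase. Start/end markers bracket the first stimulus onset and the last
#' stimulus offset on the (virtual) clock.
#'
#' @param sc A running [staircase_init()] object.
#' @param cond A [condition()].
#' @param model A [psychometric_model()].
#' @param target_position Interval (1-3) carrying the AM tone.
#' @param trial_start_s Trial start on the session clock, seconds.
#' @param stim_duration_s Stimulus duration in seconds.
#' @param onsets_s Within-trial stimulus onsets.
#' @param render_audio If `TRUE`, synthesize the three stimuli and return
#'   them; the default skips rendering, which the simulation does not need.
#' @param rate Sampling rate used when rendering.
#' @return `list(record, staircase, audio)`: `record` is a one-row data frame
#'   (`position`, `depth`, `answer`, `step`, `reversal`, `start_s`, `end_s`),
#'   `staircase` the updated object, `audio` a list of three
#'   [audio_track()]s or `NULL`.
#' @export
run_trial <- function(sc, cond, model, target_position,
                      trial_start_s = 0, stim_duration_s = 0.5,
                      onsets_s = c(0.5, 1.5, 2.5),
                      render_audio = FALSE, rate = 44100) {
  stopifnot(inherits(sc, "staircase"), inherits(cond, "amdt_condition"),
            inherits(model, "psychometric_model"),
            target_position %in% seq_along(onsets_s))
  depth <- sc$value
  answer <- simulate_answer(depth, model)
  sc2 <- staircase_update(sc, answer)
  h <- staircase_history(sc2)
  last <- h[nrow(h), ]

  audio <- NULL
  if (render_audio) {
    audio <- lapply(seq_along(onsets_s), function(i) {
      if (i == target_position)
        synthesize_am_tone(cond$carrier_hz, cond$mod_hz, depth,
                           stim_duration_s, rate)
      else
        synthesize_am_tone(cond$carrier_hz, 0, -Inf, stim_duration_s, rate)
    })
  }
  record <- data.frame(position = as.integer(target_position), depth = depth,
                       answer = answer, step = last$step,
                       reversal = last$reversal,
                       start_s = trial_start_s + onsets_s[1],
                       end_s = trial_start_s + onsets_s[length(onsets_s)] +
                         stim_duration_s)
  list(record = record, staircase = sc2, audio = audio)
}

#' Run a full simulated session
#'
#' Executes the complete 3-AFC amplitude-modulation detection session for one
#' simulated participant: the condition order is shuffled, and each condition
#' is played `repetitions` times as balanced 3 x `reps_per_position`-trial
#' blocks with a single adaptive track persisting across that condition's
#' blocks (the tracked depth is initialized once per condition). Timestamps
#' come from a deterministic virtual clock that advances by `trial_period_s`
#' per trial, so the whole session is reproducible from its seed.
#'
#' @param conditions List of [condition()]s.
#' @param participant_id Identifier stored in the result.
#' @param seed Integer seed for this session's random stream.
#' @param staircase A [staircase_config()]; its stop rules cap each
#'   condition run (default: the run's planned trial count).
#' @param observer A [psychometric_model()].
#' @param reps_per_position Target-position repetitions per block (12 gives
#'   36-trial blocks).
#' @param repetitions Plays of each condition per session (default 3).
#' @param stim_duration_s,onsets_s,trial_period_s Timeline parameters in
#'   seconds.
#' @return An object of class `"amdt_session"`: per-condition runs (each with
#'   its finished staircase and trial records), the marker stream (2 markers
#'   per trial), stimulus-file counts, the seed and a config snapshot.
#' @export
run_session <- function(conditions = default_conditions(),
                        participant_id = 1L, seed = 1L,
                        staircase = NULL,
                        observer = psychometric_model(-9, 2),
                        reps_per_position = 12, repetitions = 3,
                        stim_duration_s = 0.5, onsets_s = c(0.5, 1.5, 2.5),
                        trial_period_s = 4) {
  set.seed(as.integer(seed))
  n_block <- 3L * reps_per_position
  run_trials <- n_block * repetitions
  if (is.null(staircase))
    staircase <- staircase_config(6, c(1, 0.5), 1, n_down = 3,
                                  max_trials = run_trials)
  stopifnot(inherits(staircase, "staircase_config"),
            inherits(observer, "psychometric_model"))

  plan <- build_condition_plan(conditions, reps_per_position)
  marker_label <- character(0)
  marker_time <- numeric(0)
  clock <- 0
  runs <- list()
  for (k in seq_along(plan)) {
    cond <- plan[[k]]$condition
    positions <- plan[[k]]$positions
    if (repetitions > 1)
      positions <- c(positions, unlist(lapply(seq_len(repetitions - 1),
                       function(i) sample(rep(1:3, reps_per_position)))))
    sc <- staircase_init(staircase)
    recs <- vector("list", length(positions))
    n_run <- 0L
    for (i in seq_along(positions)) {
      if (staircase_is_finished(sc)) break
      out <- run_trial(sc, cond, observer, positions[i],
                       trial_start_s = clock,
                       stim_duration_s = stim_duration_s, onsets_s = onsets_s)
      sc <- out$staircase
      rec <- out$record
      marker_label <- c(marker_label, "start", "end")
      marker_time <- c(marker_time, rec$start_s, rec$end_s)
      rec <- cbind(data.frame(participant = participant_id,
                              carrier_hz = cond$carrier_hz,
                              mod_hz = cond$mod_hz,
                              repetition = ((i - 1L) %/% n_block) + 1L,
                              trial = i), rec)
      recs[[i]] <- rec
      clock <- clock + trial_period_s
      n_run <- i
    }
    runs[[k]] <- list(condition = cond, staircase = sc,
                      records = do.call(rbind, recs[seq_len(n_run)]))
  }
  if (is.unsorted(marker_time))
    stop_amtrack("virtual clock produced non-monotonic markers",
                 class = "amtrack_clock_error")
  markers <- data.frame(label = marker_label, timestamp_s = marker_time)
  n_trials <- sum(vapply(runs, function(r) nrow(r$records), integer(1)))
  structure(list(participant_id = participant_id, seed = as.integer(seed),
                 runs = runs, markers = markers,
                 counts = list(
                   trials = n_trials,
                   trials_per_block = n_block,
                   blocks = length(conditions) * repetitions,
                   tone_files = 3L * n_trials,
                   am_tone_files = n_trials),
                 config = list(reps_per_position = reps_per_position,
                               repetitions = repetitions,
                               stim_duration_s = stim_duration_s,
                               onsets_s = onsets_s,
                               trial_period_s = trial_period_s,
                               staircase = staircase, observer = observer)),
            class = "amdt_session")
}

#' @export
print.amdt_session <- function(x, ...) {
  cat(sprintf("<amdt_session: participant %s, %d condition runs, %d trials, %d markers (seed %d)>\n",
              format(x$participant_id), length(x$runs), x$counts$trials,
              nrow(x$markers), x$seed))
  invisible(x)
}

#' Session log as a flat data frame
#'
#' @param session An [run_session()] result.
#' @return One row per trial: participant, condition frequencies, repetition,
#'   trial index, target position, presented depth, answer, step, reversal
#'   flag, start/end marker times.
#' @export
session_log <- function(session) {
  stopifnot(inherits(session, "amdt_session"))
  do.call(rbind, lapply(session$runs, function(r) r$records))
}
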