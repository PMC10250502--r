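#' Configure a transformed up-down staircase
#'
#' Defines an n-down-1-up adaptive procedure: the tracked value is stepped
#' down after `n_down` consecutive correct responses and stepped up after a
#' single error. Step sizes follow an ordered schedule keyed to the number of
#' recorded reversals (default) or completed trials: after the count reaches
#' `change_points[i]`, `step_sizes[i + 1]` is in effect for the next executed
#' step.
#'
#' @param start_value Starting value of the tracked variable (dB).
#' @param step_sizes Ordered vector of positive step sizes (dB).
#' @param change_points Ordered vector of reversal (or trial) counts at which
#'   the next step size takes effect; must be one shorter than `step_sizes`.
#' @param n_down Consecutive correct responses required for a down step
#'   (3 targets 79.4\% correct).
#' @param n_up Errors required for an up step; only 1 is supported.
#' @param schedule_mode `"reversal"` or `"trial"`: whether `change_points`
#'   count recorded reversals or completed trials.
#' @param max_trials,max_reversals Stop rules; at least one must be set.
#' @param min_value,max_value Optional saturation bounds on the tracked value.
#' @return An object of class `"staircase_config"`.
#' @examples
#' cfg <- staircase_config(6, c(1, 0.5), 1, max_trials = 36)
#' @export
staircase_config <- function(start_value, step_sizes, change_points = numeric(0),
                             n_down = 3, n_up = 1,
                             schedule_mode = c("reversal", "trial"),
                             max_trials = NULL, max_reversals = NULL,
                             min_value = -Inf, max_value = Inf) {
  schedule_mode <- match.arg(schedule_mode)
  step_sizes <- as.numeric(step_sizes)
  change_points <- as.numeric(change_points)
  if (length(step_sizes) != length(change_points) + 1L)
    stop_amtrack("need length(step_sizes) == length(change_points) + 1 (got ",
                 length(step_sizes), " and ", length(change_points), ")",
                 class = "amtrack_config_error")
  if (any(step_sizes <= 0))
    stop_amtrack("step sizes must be positive", class = "amtrack_config_error")
  if (is.unsorted(change_points, strictly = TRUE) && length(change_points) > 1)
    stop_amtrack("change points must be strictly increasing",
                 class = "amtrack_config_error")
  if (n_down < 1 || n_down != round(n_down))
    stop_amtrack("'n_down' must be a positive integer", class = "amtrack_config_error")
  if (!identical(as.numeric(n_up), 1))
    stop_amtrack("only 1-up rules are supported (n_up = 1)",
                 class = "amtrack_config_error")
  if (is.null(max_trials) && is.null(max_reversals))
    stop_amtrack("at least one stop rule (max_trials or max_reversals) is required",
                 class = "amtrack_config_error")
  if (min_value >= max_value)
    stop_amtrack("'min_value' must be below 'max_value'", class = "amtrack_config_error")
  structure(list(start_value = start_value, step_sizes = step_sizes,
                 change_points = change_points, n_down = as.integer(n_down),
                 n_up = 1L, schedule_mode = schedule_mode,
                 max_trials = max_trials, max_reversals = max_reversals,
                 min_value = min_value, max_value = max_value),
            class = "staircase_config")
}

#' Initialize a staircase
#'
#' @param config A [staircase_config()].
#' @return An object of class `"staircase"` holding the tracked value, the
#'   consecutive-correct counter, and the (empty) trial and reversal history.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(config = config,
                 value = config$start_value,
                 consecutive_correct = 0L,
                 trial_index = 0L,
                 last_direction = "none",
                 rev_trial = integer(0), rev_value = numeric(0),
                 rev_step = numeric(0),
                 hist_trial = integer(0), hist_value = numeric(0),
                 hist_answer = logical(0), hist_step = numeric(0),
                 hist_reversal = logical(0)),
            class = "staircase")
}

#' Step size currently in effect
#'
#' @param sc A [staircase_init()] object.
#' @return The scheduled step size (dB) given the recorded reversal or
#'   completed-trial count; counts beyond the last change point saturate at
#'   the final step size.
#' @export
staircase_current_step <- function(sc) {
  stopifnot(inherits(sc, "staircase"))
  cfg <- sc$config
  count <- if (cfg$schedule_mode == "reversal") length(sc$rev_trial) else sc$trial_index
  idx <- findInterval(count, cfg$change_points) + 1L
  cfg$step_sizes[[min(idx, length(cfg$step_sizes))]]
}

#' Has a stop rule been met?
#'
#' @param sc A staircase.
#' @return `TRUE` iff the configured `max_trials` or `max_reversals` has been
#'   reached.
#' @export
staircase_is_finished <- function(sc) {
  stopifnot(inherits(sc, "staircase"))
  cfg <- sc$config
  (!is.null(cfg$max_trials) && sc$trial_index >= cfg$max_trials) ||
    (!is.null(cfg$max_reversals) && length(sc$rev_trial) >= cfg$max_reversals)
}

#' Update a staircase with one response
#'
#' Applies the n-down-1-up rule: a correct response increments the
#' consecutive-correct counter and, when it reaches `n_down`, executes a down
#' step and resets the counter; a wrong response resets the counter and
#' executes an up step. A reversal is recorded at the trial where an executed
#' step's direction differs from the previous executed step's direction (the
#' first executed step records none); the recorded reversal carries the
#' presented value and the step size that was in effect. Under the default
#' reversal-keyed schedule, recording the triggering reversal advances the
#' schedule immediately, so the new step size applies from the next executed
#' step onward.
#'
#' @param sc A staircase (not finished).
#' @param correct Logical: was the response correct?
#' @return The updated staircase.
#' @export
staircase_update <- function(sc, correct) {
  stopifnot(inherits(sc, "staircase"), is.logical(correct), length(correct) == 1L)
  if (staircase_is_finished(sc))
    stop_amtrack("staircase already finished (stop rule met)",
                 class = "amtrack_state_error")
  cfg <- sc$config
  step <- staircase_current_step(sc)
  presented <- sc$value
  sc$trial_index <- sc$trial_index + 1L

  direction <- NULL
  if (correct) {
    sc$consecutive_correct <- sc$consecutive_correct + 1L
    if (sc$consecutive_correct == cfg$n_down) {
      direction <- "down"
      sc$consecutive_correct <- 0L
    }
  } else {
    direction <- "up"
    sc$consecutive_correct <- 0L
  }

  reversal <- FALSE
  if (!is.null(direction)) {
    if (sc$last_direction != "none" && direction != sc$last_direction) {
      reversal <- TRUE
      sc$rev_trial <- c(sc$rev_trial, sc$trial_index)
      sc$rev_value <- c(sc$rev_value, presented)
      sc$rev_step <- c(sc$rev_step, step)
    }
    sc$last_direction <- direction
    delta <- if (direction == "down") -step else step
    sc$value <- min(cfg$max_value, max(cfg$min_value, sc$value + delta))
  }

  sc$hist_trial <- c(sc$hist_trial, sc$trial_index)
  sc$hist_value <- c(sc$hist_value, presented)
  sc$hist_answer <- c(sc$hist_answer, correct)
  sc$hist_step <- c(sc$hist_step, step)
  sc$hist_reversal <- c(sc$hist_reversal, reversal)
  sc
}

#' Trial-by-trial staircase history
#'
#' @param sc A staircase.
#' @return A data frame with one row per trial: `trial`, `value` (presented),
#'   `answer`, `step` (in effect), `reversal` flag.
#' @export
staircase_history <- function(sc) {
  stopifnot(inherits(sc, "staircase"))
  data.frame(trial = sc$hist_trial, value = sc$hist_value,
             answer = sc$hist_answer, step = sc$hist_step,
             reversal = sc$hist_reversal)
}

#' Recorded reversals
#'
#' @param sc A staircase.
#' @return A data frame: `trial`, `value` (presented at the reversal trial),
#'   `step` (size in effect for the reversing step).
#' @export
staircase_reversals <- function(sc) {
  stopifnot(inherits(sc, "staircase"))
  data.frame(trial = sc$rev_trial, value = sc$rev_value, step = sc$rev_step)
}

#' @export
print.staircase <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<staircase %d-down-1-up: value %.4g dB after %d trials, %d reversals%s>\n",
              cfg$n_down, x$value, x$trial_index, length(x$rev_trial),
              if (staircase_is_finished(x)) ", finished" else ""))
  invisible(x)
}

#' Plot a staircase track
#'
#' Presented value against trial index, with correct/wrong responses and
#' reversal trials marked.
#'
#' @param x A staircase.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.staircase <- function(x, ...) {
  h <- staircase_history(x)
  if (nrow(h) == 0L) stop_amtrack("empty staircase", class = "amtrack_state_error")
  graphics::plot(h$trial, h$value, type = "s", xlab = "trial",
                 ylab = "tracked value (dB)", ...)
  graphics::points(h$trial[h$answer], h$value[h$answer], pch = 1)
  graphics::points(h$trial[!h$answer], h$value[!h$answer], pch = 4, col = 2)
  graphics::points(h$trial[h$reversal], h$value[h$reversal], pch = 8, col = 3)
  invisible(x)
}
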