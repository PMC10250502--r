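# Independent replay oracle for the n-down-1-up rules, written as a direct
# transcription of the verbal procedure and kept free of package internals.
# Returns the presented value per trial, the final value, and the reversal
# trials with the step size each reversing step used.
replay_updown <- function(answers, start, steps, change_points,
                          n_down = 3, mode = "reversal") {
  value <- start
  pending_correct <- 0
  prev_move <- NA_character_
  presented <- numeric(length(answers))
  rev_trials <- integer(0)
  rev_steps <- numeric(0)
  n_reversals <- 0
  for (t in seq_along(answers)) {
    presented[t] <- value
    count <- if (mode == "reversal") n_reversals else t - 1
    k <- 1 + sum(change_points <= count)
    step <- steps[min(k, length(steps))]
    move <- NA_character_
    if (answers[t]) {
      pending_correct <- pending_correct + 1
      if (pending_correct == n_down) {
        move <- "down"
        pending_correct <- 0
      }
    } else {
      move <- "up"
      pending_correct <- 0
    }
    if (!is.na(move)) {
      if (!is.na(prev_move) && move != prev_move) {
        n_reversals <- n_reversals + 1
        rev_trials <- c(rev_trials, t)
        rev_steps <- c(rev_steps, step)
      }
      prev_move <- move
      value <- value + if (move == "down") -step else step
    }
  }
  list(presented = presented, final = value,
       rev_trials = rev_trials, rev_steps = rev_steps)
}

# Drive a package staircase with a fixed answer sequence.
drive_staircase <- function(answers, config) {
  sc <- staircase_init(config)
  for (a in answers) sc <- staircase_update(sc, a)
  sc
}

paper_staircase_config <- function(max_trials = 108) {
  staircase_config(6, c(1, 0.5), 1, n_down = 3, max_trials = max_trials)
}
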