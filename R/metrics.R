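#' Depths across the last reversals at the smallest step size
#'
#' Extracts the converged portion of a staircase run: all presented depths
#' from the trial of the `n_reversals`-th-from-last qualifying reversal
#' through the trial of the last qualifying reversal, inclusive. A reversal
#' qualifies when it was recorded while the smallest step size was in effect.
#'
#' @param run A `staircase` object, or a data frame with columns `trial`,
#'   `value`, `step`, `reversal` (as written by [session_log()] or
#'   [staircase_history()]).
#' @param n_reversals Window size in qualifying reversals (default 6).
#' @param smallest_step The qualifying step size; defaults to the smallest
#'   step in the run.
#' @param run_label Name used in error messages.
#' @return Numeric vector of presented depths in the window.
#' @export
converged_depths <- function(run, n_reversals = 6, smallest_step = NULL,
                             run_label = "run") {
  if (inherits(run, "staircase")) {
    smallest_step <- smallest_step %||% min(run$config$step_sizes)
    h <- staircase_history(run)
  } else {
    h <- as.data.frame(run)
    if (!all(c("trial", "value", "step", "reversal") %in% names(h)))
      stop_amtrack(run_label, ": need columns trial, value, step, reversal",
                   class = "amtrack_analysis_error")
    smallest_step <- smallest_step %||% min(h$step)
  }
  qual <- h$trial[h$reversal & abs(h$step - smallest_step) < 1e-9]
  if (length(qual) < n_reversals)
    stop_amtrack(run_label, ": only ", length(qual), " reversal(s) at step ",
                 smallest_step, " dB; need ", n_reversals,
                 class = "amtrack_analysis_error")
  t0 <- qual[length(qual) - n_reversals + 1L]
  t1 <- qual[length(qual)]
  h$value[h$trial >= t0 & h$trial <= t1]
}

run_windows <- function(runs, n_reversals, smallest_step) {
  if (inherits(runs, "staircase") || is.data.frame(runs)) runs <- list(runs)
  labels <- names(runs) %||% paste0("run ", seq_along(runs))
  lapply(seq_along(runs), function(j)
    converged_depths(runs[[j]], n_reversals, smallest_step, labels[[j]]))
}

#' Convergence estimation across staircase runs
#'
#' Per run, the mean presented depth over the window returned by
#' [converged_depths()]; the estimate is the average of these per-run means
#' over all runs.
#'
#' @param runs A list of runs (see [converged_depths()]), or a single run.
#' @param n_reversals,smallest_step Window definition.
#' @return `list(estimate, run_means)`.
#' @export
convergence_estimation <- function(runs, n_reversals = 6, smallest_step = NULL) {
  w <- run_windows(runs, n_reversals, smallest_step)
  run_means <- vapply(w, mean, numeric(1))
  list(estimate = mean(run_means), run_means = run_means)
}

#' Convergence variability across staircase runs
#'
#' Per run, the population standard deviation (1/N divisor) of the window
#' depths; averaged over runs.
#'
#' @inheritParams convergence_estimation
#' @return Mean of the per-run standard deviations, in dB.
#' @export
convergence_variability <- function(runs, n_reversals = 6, smallest_step = NULL) {
  w <- run_windows(runs, n_reversals, smallest_step)
  mean(vapply(w, pop_sd, numeric(1)))
}

#' Estimation variability across staircase runs
#'
#' Deviations of the per-run converged means from a target depth,
#' `diff(j) = mean(j) - target`, summarized by their population standard
#' deviation about their own mean. Because the target enters every deviation
#' identically, the result does not depend on it; it is reported for
#' interpretability.
#'
#' @inheritParams convergence_estimation
#' @param target_depth Target convergence depth in dB.
#' @return Population standard deviation of the per-run deviations, in dB.
#' @export
estimation_variability <- function(runs, target_depth,
                                   n_reversals = 6, smallest_step = NULL) {
  w <- run_windows(runs, n_reversals, smallest_step)
  if (length(w) < 2)
    stop_amtrack("need at least two runs (got ", length(w), ")",
                 class = "amtrack_analysis_error")
  diffs <- vapply(w, mean, numeric(1)) - target_depth
  pop_sd(diffs)
}

#' Full convergence report
#'
#' Bundles the per-run window statistics and the three aggregate measures --
#' convergence estimation, convergence variability, and estimation
#' variability -- for a set of staircase runs.
#'
#' @inheritParams estimation_variability
#' @return An object of class `"convergence_report"` with fields `runs` (a
#'   data frame of per-run `depth_mean`, `depth_std`, `n_trials`),
#'   `convergence_estimation`, `convergence_variability`,
#'   `estimation_variability` (NA with a warning when only one run is given),
#'   `target_depth`, `M`, `n_reversals`.
#' @export
convergence_report <- function(runs, target_depth,
                               n_reversals = 6, smallest_step = NULL) {
  w <- run_windows(runs, n_reversals, smallest_step)
  per_run <- data.frame(
    run = seq_along(w),
    depth_mean = vapply(w, mean, numeric(1)),
    depth_std = vapply(w, pop_sd, numeric(1)),
    n_trials = lengths(w))
  est_var <- if (length(w) >= 2) pop_sd(per_run$depth_mean - target_depth) else {
    warning("estimation variability undefined for a single run")
    NA_real_
  }
  structure(list(runs = per_run,
                 convergence_estimation = mean(per_run$depth_mean),
                 convergence_variability = mean(per_run$depth_std),
                 estimation_variability = est_var,
                 target_depth = target_depth,
                 M = length(w), n_reversals = n_reversals),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, digits = 4, ...) {
  cat("Staircase convergence report (", x$M, " runs, last ", x$n_reversals,
      " smallest-step reversals)\n", sep = "")
  cat(sprintf("  convergence estimation : %.*f dB (target %.*f dB)\n",
              digits, x$convergence_estimation, digits, x$target_depth))
  cat(sprintf("  convergence variability: %.*f dB\n",
              digits, x$convergence_variability))
  cat(sprintf("  estimation variability : %.*f dB\n",
              digits, x$estimation_variability))
  invisible(x)
}
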