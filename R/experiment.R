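#' Run the simulated 3-AFC amplitude-modulation detection experiment
#'
#' The package's front end: simulates the full validation design -- by
#' default ten participants, each tested on the four carrier/modulation
#' conditions with a 3-down-1-up staircase starting at 6 dB (step 1 dB, then
#' 0.5 dB after the first reversal) against the cumulative-Gaussian observer
#' (midpoint -9 dB, std 2 dB) -- and summarizes the adaptive tracks by their
#' converged behavior over the last six smallest-step reversals.
#'
#' Each participant's random stream is seeded with `seed + participant index`,
#' so results are reproducible and participants are independent.
#'
#' @param conditions List of [condition()]s (default: the four standard
#'   carrier 400/1000 Hz x modulation 5/10 Hz conditions).
#' @param n_participants Number of simulated participants.
#' @param observer A [psychometric_model()].
#' @param staircase A [staircase_config()] (default: the design above).
#' @param reps_per_position,repetitions,stim_duration_s,onsets_s,trial_period_s
#'   Session parameters; see [run_session()].
#' @param n_reversals Converged-window size in smallest-step reversals.
#' @param seed Base integer seed.
#' @return An object of class `"amdt_experiment"` with `sessions` (a list of
#'   [run_session()] results), `report` (a [convergence_report()] across all
#'   condition runs), `target_depth`, and the design parameters. Supports
#'   `print()`, `summary()`, `coef()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' fit <- amdt_experiment(n_participants = 2, seed = 42)
#' coef(fit)
#' summary(fit)
#' @export
amdt_experiment <- function(conditions = default_conditions(),
                            n_participants = 10,
                            observer = psychometric_model(-9, 2),
                            staircase = NULL,
                            reps_per_position = 12, repetitions = 3,
                            stim_duration_s = 0.5,
                            onsets_s = c(0.5, 1.5, 2.5), trial_period_s = 4,
                            n_reversals = 6, seed = 1) {
  cl <- match.call()
  seed <- as.integer(seed)
  sessions <- lapply(seq_len(n_participants), function(p)
    run_session(conditions, participant_id = p, seed = seed + p,
                staircase = staircase, observer = observer,
                reps_per_position = reps_per_position,
                repetitions = repetitions, stim_duration_s = stim_duration_s,
                onsets_s = onsets_s, trial_period_s = trial_period_s))
  runs <- unlist(lapply(sessions, function(s)
    lapply(s$runs, function(r) r$staircase)), recursive = FALSE)
  names(runs) <- unlist(lapply(sessions, function(s)
    vapply(s$runs, function(r)
      sprintf("participant %s, %g Hz / %g Hz", format(s$participant_id),
              r$condition$carrier_hz, r$condition$mod_hz), character(1))))
  sc_cfg <- sessions[[1]]$config$staircase
  target <- expected_convergence_depth(observer, sc_cfg$n_down)
  report <- convergence_report(runs, target_depth = target,
                               n_reversals = n_reversals)
  structure(list(call = cl, sessions = sessions, report = report,
                 observer = observer, staircase_config = sc_cfg,
                 target_depth = target, conditions = conditions,
                 n_participants = n_participants, seed = seed,
                 design = list(reps_per_position = reps_per_position,
                               repetitions = repetitions,
                               n_reversals = n_reversals)),
            class = "amdt_experiment")
}

#' @export
print.amdt_experiment <- function(x, digits = 4, ...) {
  cat("Simulated 3-AFC amplitude-modulation detection experiment\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("Design: %d participants x %d conditions, %d trials per condition run\n",
              x$n_participants, length(x$conditions),
              x$design$repetitions * 3 * x$design$reps_per_position))
  cat(sprintf("Observer: midpoint %g dB, std %g dB; target convergence %.*f dB\n",
              x$observer$midpoint, x$observer$std, digits, x$target_depth))
  cat(sprintf("Threshold estimate: %.*f dB\n", digits,
              x$report$convergence_estimation))
  invisible(x)
}

#' @export
coef.amdt_experiment <- function(object, ...) {
  c(threshold_db = object$report$convergence_estimation)
}

#' @export
residuals.amdt_experiment <- function(object, ...) {
  object$report$runs$depth_mean - object$target_depth
}

#' @export
summary.amdt_experiment <- function(object, ...) {
  structure(list(experiment = object, report = object$report),
            class = "summary.amdt_experiment")
}

#' @export
print.summary.amdt_experiment <- function(x, digits = 4, ...) {
  print(x$experiment, digits = digits)
  cat("\n")
  print(x$report, digits = digits)
  cat("\nPer-run converged means (dB):\n")
  print(summary(x$report$runs$depth_mean), digits = digits)
  invisible(x)
}

#' Plot an experiment
#'
#' `which = "runs"` shows the per-run converged mean with its per-run
#' standard deviation as error bars, against the expected convergence depth;
#' `which = "track"` shows the first participant's first staircase track.
#'
#' @param x An [amdt_experiment()] object.
#' @param which `"runs"` or `"track"`.
#' @param ... Passed to the underlying plot.
#' @export
plot.amdt_experiment <- function(x, which = c("runs", "track"), ...) {
  which <- match.arg(which)
  if (which == "track") {
    plot(x$sessions[[1]]$runs[[1]]$staircase,
         main = "First condition run", ...)
    graphics::abline(h = x$target_depth, lty = 2, col = 3)
    return(invisible(x))
  }
  r <- x$report$runs
  graphics::plot(r$run, r$depth_mean,
                 ylim = range(r$depth_mean - r$depth_std,
                              r$depth_mean + r$depth_std, x$target_depth),
                 xlab = "condition run", ylab = "converged depth (dB)",
                 pch = 19, ...)
  graphics::arrows(r$run, r$depth_mean - r$depth_std,
                   r$run, r$depth_mean + r$depth_std,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = x$target_depth, lty = 2, col = 3)
  invisible(x)
}

#' Simulate replicate experiments
#'
#' Re-runs the whole design `nsim` times with fresh base seeds and returns
#' the per-run converged means of each replicate, for studying the sampling
#' distribution of the convergence statistics.
#'
#' @param object An [amdt_experiment()].
#' @param nsim Number of replicate experiments.
#' @param seed Base seed for the replicates (default: the object's seed + 1000).
#' @param ... Unused.
#' @return A data frame with columns `sim`, `run`, `depth_mean`.
#' @export
simulate.amdt_experiment <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- as.integer(seed %||% (object$seed + 1000L))
  out <- lapply(seq_len(nsim), function(s) {
    fit <- amdt_experiment(conditions = object$conditions,
                           n_participants = object$n_participants,
                           observer = object$observer,
                           staircase = object$staircase_config,
                           reps_per_position = object$design$reps_per_position,
                           repetitions = object$design$repetitions,
                           n_reversals = object$design$n_reversals,
                           seed = seed + (s - 1L) * object$n_participants)
    data.frame(sim = s, run = fit$report$runs$run,
               depth_mean = fit$report$runs$depth_mean)
  })
  do.call(rbind, out)
}
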