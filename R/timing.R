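#' Generate synthetic paired timestamp streams
#'
#' Emulates a loopback timing audit: physical stimulus onsets lie on the
#' session grid (`first_onset_s + (i-1) * event_period_s`), and the
#' corresponding event markers lag them by a constant latency plus Gaussian
#' jitter. Used to validate [timing_report()] against known injected
#' parameters.
#'
#' @param n_events Events per run.
#' @param latency_s Systematic marker latency in seconds.
#' @param jitter_sd_s Standard deviation of the random timing error, seconds.
#' @param n_runs Number of runs (e.g. simulated participants).
#' @param seed Optional integer seed.
#' @param event_period_s,first_onset_s Session grid parameters, seconds.
#' @return `list(onsets, markers)`, each a list of `n_runs` numeric vectors.
#' @export
generate_timing_streams <- function(n_events = 48, latency_s = 0.01,
                                    jitter_sd_s = 0.002, n_runs = 10,
                                    seed = NULL, event_period_s = 4,
                                    first_onset_s = 0.5) {
  if (jitter_sd_s < 0)
    stop_amtrack("'jitter_sd_s' must be non-negative", class = "amtrack_spec_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- first_onset_s + (seq_len(n_events) - 1) * event_period_s
  onsets <- replicate(n_runs, grid, simplify = FALSE)
  markers <- lapply(onsets, function(o)
    o + latency_s + stats::rnorm(length(o), 0, jitter_sd_s))
  list(onsets = onsets, markers = markers)
}

#' Latency and jitter report for paired timestamp streams
#'
#' For each run j and event i the timing difference is
#' `diff(i,j) = marker(i,j) - onset(i,j)`; the per-run mean latency is the
#' average of these differences, and subtracting it yields the random error
#' (zero-mean within each run by construction). The standard error of the
#' mean is the population standard deviation of the per-run latencies across
#' runs; quartiles of the pooled random error use linear interpolation
#' between order statistics.
#'
#' @param markers,onsets Lists of per-run timestamp vectors (seconds),
#'   index-aligned within each run; single vectors are treated as one run.
#' @return An object of class `"timing_report"`: `diffs`, `x_mean` (per-run
#'   latency), `random_error` (per run), `mean_latency`, `sem`, `quartiles`
#'   (25/50/75% of pooled random error), `iqr`, `M`, `N`.
#' @export
timing_report <- function(markers, onsets) {
  if (is.numeric(markers)) markers <- list(markers)
  if (is.numeric(onsets)) onsets <- list(onsets)
  if (length(markers) != length(onsets))
    stop_amtrack("got ", length(markers), " marker run(s) but ",
                 length(onsets), " onset run(s)", class = "amtrack_pairing_error")
  diffs <- vector("list", length(markers))
  for (j in seq_along(markers)) {
    if (length(markers[[j]]) != length(onsets[[j]]))
      stop_amtrack("run ", j, ": ", length(markers[[j]]), " markers vs ",
                   length(onsets[[j]]), " onsets", class = "amtrack_pairing_error")
    diffs[[j]] <- markers[[j]] - onsets[[j]]
  }
  x_mean <- vapply(diffs, mean, numeric(1))
  random_error <- lapply(seq_along(diffs), function(j) diffs[[j]] - x_mean[j])
  pooled <- unlist(random_error)
  q <- stats::quantile(pooled, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(diffs = diffs, x_mean = x_mean, random_error = random_error,
                 mean_latency = mean(x_mean), sem = pop_sd(x_mean),
                 quartiles = q, iqr = q[3] - q[1],
                 M = length(diffs), N = lengths(diffs)),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat("Event-timing report (", x$M, " runs)\n", sep = "")
  cat(sprintf("  mean latency : %.4f s (SEM %.4f s)\n", x$mean_latency, x$sem))
  cat(sprintf("  random error quartiles: %.2f / %.2f / %.2f ms (IQR %.2f ms)\n",
              1e3 * x$quartiles[1], 1e3 * x$quartiles[2],
              1e3 * x$quartiles[3], 1e3 * x$iqr))
  invisible(x)
}

#' Detect stimulus onsets in a waveform
#'
#' Smooths the rectified waveform with a causal moving average and reports
#' the times where the envelope first rises above a fraction of its maximum,
#' enforcing a refractory gap between onsets.
#'
#' @param track An [audio_track()].
#' @param threshold_frac Fraction of the peak envelope (0-1, exclusive).
#' @param min_gap_s Minimum separation between reported onsets, seconds.
#' @param smooth_s Moving-average window, seconds.
#' @return Numeric vector of onset times in seconds (empty for silence).
#' @export
detect_onsets <- function(track, threshold_frac = 0.1, min_gap_s = 0.25,
                          smooth_s = 0.005) {
  stopifnot(inherits(track, "audio_track"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop_amtrack("'threshold_frac' must be in (0, 1)", class = "amtrack_spec_error")
  env <- abs(track$samples)
  if (max(env) == 0) return(numeric(0))
  w <- max(1L, as.integer(round_half_away(smooth_s * track$rate)))
  cs <- cumsum(env)
  sm <- (cs - c(rep(0, w), utils::head(cs, -w))) /
    pmin(seq_along(env), w)                       # causal mean, warm-up aware
  thr <- threshold_frac * max(sm)
  above <- sm >= thr
  rises <- which(above & !c(FALSE, utils::head(above, -1L)))
  gap <- min_gap_s * track$rate
  onset_idx <- integer(0)
  for (i in rises) {
    if (length(onset_idx) == 0L || i - onset_idx[length(onset_idx)] >= gap)
      onset_idx <- c(onset_idx, i)
  }
  (onset_idx - 1L) / track$rate
}
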