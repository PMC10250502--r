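#' Monaural audio track
#'
#' Lightweight container for a single-channel waveform: a numeric sample
#' vector (dimensionless amplitude) plus its sampling rate in Hz. All stimulus
#' operations in the package consume and return `audio_track` objects.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `"audio_track"`.
#' @examples
#' tr <- audio_track(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(tr)
#' @export
audio_track <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_amtrack("'rate' must be a single positive number", class = "amtrack_spec_error")
  if (length(samples) == 0L)
    stop_amtrack("'samples' must be non-empty", class = "amtrack_spec_error")
  if (!all(is.finite(samples)))
    stop_amtrack("'samples' must be finite", class = "amtrack_spec_error")
  structure(list(samples = samples, rate = rate), class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track: %d samples @ %g Hz (%.4g s), RMS %.4g>\n",
              length(x$samples), x$rate, duration(x), rms(x$samples)))
  invisible(x)
}

#' @rdname audio_track
#' @param x An `audio_track`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_track"))
  length(x$samples) / x$rate
}

#' Synthesize a sinusoidally amplitude-modulated tone
#'
#' Generates \eqn{s(t) = (1 + m \sin 2\pi f_{mod} t)\,\sin 2\pi f_c t} and
#' normalizes it to unit RMS. The modulation index is
#' \eqn{m = 10^{depth/20}}, the standard dB convention for modulation depth
#' (0 dB = full modulation). For synthesis `m` is clamped to [0, 1] so the
#' waveform stays physical; a tracked depth above 0 dB is thus rendered fully
#' modulated while the tracking value itself is never altered.
#'
#' @param carrier_hz Carrier frequency in Hz (> 0).
#' @param mod_hz Modulation frequency in Hz (>= 0); 0 yields a pure tone.
#' @param depth_db Modulation depth in dB, `20*log10(m)`. `-Inf` disables
#'   modulation.
#' @param duration_s Duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @return A unit-RMS [audio_track()] with an `am_spec` attribute recording
#'   the synthesis parameters.
#' @examples
#' am <- synthesize_am_tone(400, 5, depth_db = -6.0206, duration_s = 0.5)
#' sqrt(mean(am$samples^2))  # 1
#' @export
synthesize_am_tone <- function(carrier_hz, mod_hz = 0, depth_db = 0,
                               duration_s = 0.5, rate = 44100) {
  if (!is.finite(carrier_hz) || carrier_hz <= 0)
    stop_amtrack("'carrier_hz' must be positive", class = "amtrack_spec_error")
  if (!is.finite(mod_hz) || mod_hz < 0)
    stop_amtrack("'mod_hz' must be non-negative", class = "amtrack_spec_error")
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_amtrack("'duration_s' must be positive", class = "amtrack_spec_error")
  if (!is.finite(rate) || rate <= 0)
    stop_amtrack("'rate' must be positive", class = "amtrack_spec_error")
  m <- min(1, 10^(depth_db / 20))         # depth_db = -Inf -> m = 0
  n <- round_half_away(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  s <- (1 + m * sin(2 * pi * mod_hz * t)) * sin(2 * pi * carrier_hz * t)
  out <- normalize_rms(audio_track(s, rate))
  attr(out, "am_spec") <- list(carrier_hz = carrier_hz, mod_hz = mod_hz,
                               depth_db = depth_db, duration_s = duration_s,
                               rate = rate, m = m)
  out
}

#' Normalize a track to unit RMS
#'
#' Rescales the waveform by a positive scalar so that its root-mean-square
#' value is exactly 1, the package's reference level for all dB gains.
#'
#' @param track An [audio_track()].
#' @return The rescaled track.
#' @export
normalize_rms <- function(track) {
  stopifnot(inherits(track, "audio_track"))
  r <- rms(track$samples)
  if (r == 0)
    stop_amtrack("cannot normalize an all-zero track",
                 class = "amtrack_degenerate_signal")
  audio_track(track$samples / r, track$rate)
}

#' Downmix a multichannel buffer to mono
#'
#' Channels are summed sample-by-sample into one channel.
#'
#' @param x A samples-by-channels numeric matrix, a list of equal-length
#'   channel vectors, or a plain numeric vector (already mono).
#' @param rate Sampling rate in Hz.
#' @return A mono [audio_track()].
#' @export
downmix_to_mono <- function(x, rate) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L)
      stop_amtrack("need at least one channel", class = "amtrack_format_error")
    lens <- lengths(x)
    if (length(unique(lens)) != 1L)
      stop_amtrack("ragged channel lengths: ", paste(lens, collapse = ", "),
                   class = "amtrack_format_error")
    x <- do.call(cbind, x)
  }
  if (is.matrix(x)) {
    samples <- rowSums(x)
  } else if (is.numeric(x)) {
    samples <- x
  } else {
    stop_amtrack("unsupported input type", class = "amtrack_format_error")
  }
  audio_track(samples, rate)
}

#' Band-limited resampling
#'
#' Resamples a track to a new rate by spectral (FFT) interpolation: the
#' discrete spectrum is truncated or zero-padded at the smaller Nyquist
#' frequency and inverted at the new length. For band-limited signals such as
#' the tone stimuli produced by this package the method is exact up to edge
#' effects of the implicit periodic extension; duration is preserved within
#' one sample period.
#'
#' @param track An [audio_track()].
#' @param target_rate New sampling rate in Hz (> 0).
#' @return The resampled [audio_track()]. If `target_rate` equals the track
#'   rate the input is returned unchanged.
#' @export
resample_track <- function(track, target_rate) {
  stopifnot(inherits(track, "audio_track"))
  if (!is.finite(target_rate) || target_rate <= 0)
    stop_amtrack("'target_rate' must be positive", class = "amtrack_spec_error")
  if (target_rate == track$rate) return(track)
  x <- track$samples
  n <- length(x)
  n_out <- max(1L, as.integer(round_half_away(n * target_rate / track$rate)))
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  h <- floor(min(n, n_out) / 2)
  Y[seq_len(h + 1)] <- X[seq_len(h + 1)]
  if (h > 0) Y[(n_out - h + 1):n_out] <- X[(n - h + 1):n]
  # drop the unpaired Nyquist bin when downsampling to an even length
  if (n_out < n && n_out %% 2 == 0) Y[h + 1] <- Re(Y[h + 1])
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_track(y, target_rate)
}

#' Apply a gain in decibels
#'
#' Scales the waveform by `10^(level_db/20)`. Levels are relative to the
#' unit-RMS baseline established by [normalize_rms()].
#'
#' @param track An [audio_track()].
#' @param level_db Gain in dB.
#' @export
apply_level <- function(track, level_db) {
  stopifnot(inherits(track, "audio_track"), is.finite(level_db))
  audio_track(track$samples * 10^(level_db / 20), track$rate)
}

#' Mix schedule entry
#'
#' One scheduled playback event: a unit-RMS track, its level in dB, the
#' 0-based output channel, and the onset time from buffer start.
#'
#' @param track An [audio_track()].
#' @param level_db Playback level in dB relative to unit RMS.
#' @param channel 0-based output channel index.
#' @param onset_s Onset time in seconds (>= 0).
#' @export
mix_entry <- function(track, level_db = 0, channel = 0, onset_s = 0) {
  stopifnot(inherits(track, "audio_track"))
  if (channel < 0 || channel != round(channel))
    stop_amtrack("'channel' must be a non-negative integer",
                 class = "amtrack_config_error")
  if (onset_s < 0)
    stop_amtrack("'onset_s' must be non-negative", class = "amtrack_config_error")
  structure(list(track = track, level_db = level_db,
                 channel = as.integer(channel), onset_s = onset_s),
            class = "mix_entry")
}

#' Mix scheduled tracks into a multichannel buffer
#'
#' Each entry's track is scaled by its level and added (superposed) into its
#' output channel starting at the sample index nearest its onset. Regions with
#' no scheduled audio are exactly zero.
#'
#' @param entries List of [mix_entry()] objects (possibly empty).
#' @param n_channels Number of output channels.
#' @param rate Output sampling rate in Hz. Entry tracks must already be at
#'   this rate (use [resample_track()] first).
#' @param duration_s Buffer duration in seconds.
#' @return A samples-by-channels numeric matrix with attribute `rate`.
#' @export
mix_tracks <- function(entries, n_channels, rate, duration_s) {
  stopifnot(n_channels >= 1, rate > 0, duration_s > 0)
  n <- round_half_away(duration_s * rate)
  buf <- matrix(0, nrow = n, ncol = n_channels)
  for (e in entries) {
    stopifnot(inherits(e, "mix_entry"))
    if (e$channel >= n_channels)
      stop_amtrack("entry channel ", e$channel, " out of range (n_channels = ",
                   n_channels, ")", class = "amtrack_config_error")
    if (e$track$rate != rate)
      stop_amtrack("entry track rate ", e$track$rate,
                   " differs from mix rate ", rate, "; resample first",
                   class = "amtrack_config_error")
    start <- round_half_away(e$onset_s * rate)   # 0-based sample offset
    len <- length(e$track$samples)
    if (start + len > n)
      stop_amtrack("entry overruns buffer: onset ", e$onset_s, " s + ",
                   len / rate, " s > ", duration_s, " s",
                   class = "amtrack_schedule_error")
    idx <- (start + 1):(start + len)
    col <- e$channel + 1L
    buf[idx, col] <- buf[idx, col] + e$track$samples * 10^(e$level_db / 20)
  }
  attr(buf, "rate") <- rate
  buf
}
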