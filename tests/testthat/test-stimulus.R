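test_that("AM tone synthesis follows the depth convention and is unit RMS", {
  # depth 0 dB -> full modulation, -20 dB -> m = 0.1, -6.0206 dB -> m = 0.5
  expect_equal(attr(synthesize_am_tone(400, 5, 0, 0.1), "am_spec")$m, 1)
  expect_equal(attr(synthesize_am_tone(400, 5, -20, 0.1), "am_spec")$m, 0.1)
  am <- synthesize_am_tone(400, 5, -6.0206, 1, 44100)
  expect_equal(attr(am, "am_spec")$m, 0.5, tolerance = 1e-5)
  expect_equal(sqrt(mean(am$samples^2)), 1, tolerance = 1e-9)
  expect_length(am$samples, 44100)

  # above 0 dB the synthesis index clamps to 1 but the spec records the depth
  over <- synthesize_am_tone(400, 5, 6, 0.1)
  expect_equal(attr(over, "am_spec")$m, 1)
  expect_equal(attr(over, "am_spec")$depth_db, 6)

  # mod_hz = 0 and m = 0 both reduce to the pure carrier
  pure <- synthesize_am_tone(400, 0, 0, 0.2)
  silent_mod <- synthesize_am_tone(400, 5, -Inf, 0.2)
  expect_equal(pure$samples, silent_mod$samples, tolerance = 1e-12)

  expect_error(synthesize_am_tone(400, 5, 0, duration_s = 0),
               class = "amtrack_spec_error")
  expect_error(synthesize_am_tone(400, 5, 0, 0.5, rate = -1),
               class = "amtrack_spec_error")
  expect_error(synthesize_am_tone(0, 5, 0, 0.5), class = "amtrack_spec_error")
})

test_that("RMS normalization rescales by a positive scalar to unit RMS", {
  tone <- audio_track(0.3 * sin(2 * pi * 50 * (0:9999) / 8000), 8000)
  out <- normalize_rms(tone)
  expect_equal(sqrt(mean(out$samples^2)), 1, tolerance = 1e-9)
  # a sine of amplitude A maps to amplitude sqrt(2)
  expect_equal(max(abs(out$samples)), sqrt(2), tolerance = 1e-3)
  # idempotent on an already-normalized track
  expect_equal(normalize_rms(out)$samples, out$samples)
  # shape preserved: output proportional to input
  expect_equal(cor(out$samples, tone$samples), 1)
  expect_error(normalize_rms(audio_track(rep(0, 10), 8000)),
               class = "amtrack_degenerate_signal")

  set.seed(11)
  for (i in 1:20) {
    x <- audio_track(rnorm(1000, sd = runif(1, 0.01, 10)), 44100)
    expect_equal(sqrt(mean(normalize_rms(x)$samples^2)), 1, tolerance = 1e-9)
  }
})

test_that("downmix sums channels samplewise", {
  L <- sin(2 * pi * 100 * (0:999) / 8000)
  expect_equal(downmix_to_mono(cbind(L, L), 8000)$samples, 2 * L)
  expect_equal(downmix_to_mono(list(L), 8000)$samples, L)
  # opposite-phase channels cancel to exact zeros
  expect_true(all(downmix_to_mono(cbind(L, -L), 8000)$samples == 0))
  expect_error(downmix_to_mono(list(L, L[-1]), 8000),
               class = "amtrack_format_error")
})

test_that("resampling preserves duration, band-limited content and energy", {
  t44 <- (0:44099) / 44100
  x <- audio_track(sin(2 * pi * 100 * t44), 44100)
  expect_identical(resample_track(x, 44100), x)          # pass-through

  up <- resample_track(x, 48000)
  expect_length(up$samples, 48000)
  expect_equal(duration(up), 1)

  down <- resample_track(x, 22050)
  ref <- sin(2 * pi * 100 * (0:22049) / 22050)
  expect_gt(cor(down$samples, ref), 0.999)
  expect_equal(mean(down$samples^2) / mean(x$samples^2), 1, tolerance = 0.01)
  expect_equal(mean(up$samples^2) / mean(x$samples^2), 1, tolerance = 0.01)

  expect_error(resample_track(x, 0), class = "amtrack_spec_error")
})

test_that("dB gains scale amplitudes as 10^(dB/20)", {
  x <- audio_track(rnorm(100), 8000)
  expect_equal(apply_level(x, 0)$samples, x$samples)
  expect_equal(apply_level(x, -20)$samples, 0.1 * x$samples)
  expect_equal(apply_level(x, 6.0206)$samples, 2 * x$samples, tolerance = 1e-6)
})

test_that("mixing schedules, superposes and zero-fills correctly", {
  rate <- 44100
  empty <- mix_tracks(list(), 2, rate, 1)
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(44100L, 2L))

  tone <- synthesize_am_tone(400, 0, -Inf, 0.2, rate)
  e <- mix_entry(tone, level_db = 0, channel = 1, onset_s = 0.5)
  buf <- mix_tracks(list(e), 2, rate, 1)
  # onset sample = round(0.5 * 44100): everything before is exactly zero and
  # the entry's samples land verbatim from there
  expect_true(all(buf[1:22050, 2] == 0))
  expect_equal(buf[22051:(22050 + length(tone$samples)), 2], tone$samples)
  expect_true(all(buf[, 1] == 0))       # untouched channel exactly zero

  # superposition: two identical entries give exactly twice one entry
  buf2 <- mix_tracks(list(e, e), 2, rate, 1)
  expect_identical(buf2, buf + buf)

  # linearity across disjoint entry sets
  tone2 <- synthesize_am_tone(900, 0, -Inf, 0.2, rate)
  f <- mix_entry(tone2, level_db = -6, channel = 0, onset_s = 0.1)
  expect_equal(mix_tracks(list(e, f), 2, rate, 1),
               mix_tracks(list(e), 2, rate, 1) + mix_tracks(list(f), 2, rate, 1))

  # energy over an isolated entry's support equals its level gain
  g <- mix_entry(tone, level_db = -20, channel = 0, onset_s = 0.25)
  bufg <- mix_tracks(list(g), 1, rate, 1)
  support <- 11026:(11025 + length(tone$samples))
  expect_equal(sqrt(mean(bufg[support, 1]^2)), 0.1, tolerance = 1e-6)

  expect_error(mix_tracks(list(mix_entry(tone, channel = 2)), 2, rate, 1),
               class = "amtrack_config_error")
  expect_error(mix_tracks(list(mix_entry(tone, onset_s = 0.9)), 1, rate, 1),
               class = "amtrack_schedule_error")
})

test_that("SPL calibration inverts the measured per-channel offset", {
  prof <- calibration_profile(c(`0` = 5, `1` = 0), "unit test reference")
  expect_equal(calibrate_level(70, 0, prof), 65)
  expect_equal(calibrate_level(70, 1, prof), 70)
  expect_error(calibrate_level(70, 3, prof),
               class = "amtrack_calibration_missing")
  # round trip: software level + offset recovers the target exactly
  for (target in c(40, 65, 80.5)) {
    lvl <- calibrate_level(target, 0, prof)
    expect_identical(lvl + prof$offsets_db[["0"]], target)
  }
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_profile(prof, path)
  back <- read_calibration_profile(path)
  expect_equal(back$offsets_db, prof$offsets_db)
  expect_equal(back$reference, prof$reference)
})

test_that("WAV files round-trip in float32 and read back as PCM16", {
  tone <- synthesize_am_tone(440, 7, -3, 0.1, 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(tone, path)
  back <- read_wav(path)
  expect_s3_class(back, "audio_track")
  expect_equal(back$rate, 8000)
  expect_equal(back$samples, tone$samples, tolerance = 1e-7)  # float32 quantum

  # 16-bit PCM path (values scaled into [-1, 1])
  small <- audio_track(0.5 * sin(2 * pi * 100 * (0:799) / 8000), 8000)
  write_wav(small, path, format = "pcm16")
  back16 <- read_wav(path)
  expect_equal(back16$samples, small$samples, tolerance = 1e-4)

  # stereo round trip comes back as a matrix suitable for downmixing
  m <- cbind(small$samples, -small$samples)
  write_wav(m, path, rate = 8000)
  backm <- read_wav(path)
  expect_true(is.matrix(backm))
  expect_equal(attr(backm, "rate"), 8000)
  expect_equal(dim(backm), c(800L, 2L))
})
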