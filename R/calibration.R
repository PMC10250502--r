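#' Per-channel SPL calibration profile
#'
#' Maps between software playback level (dB re unit RMS) and measured sound
#' pressure level. The offset for a channel is the measured SPL minus the
#' nominal software level of the calibration signal on that channel;
#' [calibrate_level()] then solves for the software level that produces a
#' requested SPL.
#'
#' @param offsets_db Numeric vector of per-channel offsets in dB, named by
#'   0-based channel index (names default to `0, 1, ...` in order).
#' @param reference Free-text description of the calibration reference
#'   (signal, meter, date).
#' @return An object of class `"calibration_profile"`.
#' @examples
#' prof <- calibration_profile(c(`0` = 5, `1` = 4.5), "pink noise, class-1 meter")
#' calibrate_level(70, channel = 0, prof)  # 65
#' @export
calibration_profile <- function(offsets_db, reference = "") {
  offsets_db <- unlist(offsets_db)
  if (length(offsets_db) == 0L || !all(is.finite(offsets_db)))
    stop_amtrack("offsets must be finite and non-empty",
                 class = "amtrack_config_error")
  if (is.null(names(offsets_db)) || any(names(offsets_db) == ""))
    names(offsets_db) <- as.character(seq_along(offsets_db) - 1L)
  structure(list(offsets_db = offsets_db, reference = as.character(reference)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  for (ch in names(x$offsets_db))
    cat(sprintf("  channel %s: offset %+.2f dB\n", ch, x$offsets_db[[ch]]))
  if (nzchar(x$reference)) cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' Software level for a target SPL
#'
#' @param target_spl Target sound pressure level in dB SPL.
#' @param channel 0-based output channel.
#' @param profile A [calibration_profile()] covering `channel`.
#' @return The software level in dB: `target_spl - offset_db[channel]`.
#' @export
calibrate_level <- function(target_spl, channel, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  key <- as.character(channel)
  if (!key %in% names(profile$offsets_db))
    stop_amtrack("no calibration offset for channel ", key,
                 class = "amtrack_calibration_missing")
  target_spl - profile$offsets_db[[key]]
}

#' Read/write a calibration profile as JSON
#'
#' The on-disk form is `{"offsets_db": {"<channel>": dB, ...},
#' "reference": "..."}`.
#'
#' @param path File path.
#' @param profile A [calibration_profile()].
#' @return `read_calibration_profile()` returns a [calibration_profile()];
#'   `write_calibration_profile()` returns `path` invisibly.
#' @export
read_calibration_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(obj$offsets_db, obj$reference %||% "")
}

#' @rdname read_calibration_profile
#' @export
write_calibration_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(list(offsets_db = as.list(profile$offsets_db),
                            reference = profile$reference),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
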