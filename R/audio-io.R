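# Minimal RIFF/WAVE reader and writer.
#
# Supports the two dialects the toolkit needs: 16-bit integer PCM (format
# code 1) and 32-bit IEEE float (format code 3), mono or multichannel,
# little-endian. Stimulus files are written as 32-bit float mono so that
# unit-RMS waveforms (peak amplitude sqrt(2)) round-trip without clipping.

#' Read a WAV file
#'
#' @param path Path to a RIFF/WAVE file (16-bit PCM or 32-bit IEEE float).
#' @return A mono [audio_track()], or for multichannel files a
#'   samples-by-channels matrix with attribute `rate` (pass it through
#'   [downmix_to_mono()] to obtain a track).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_amtrack(path, ": not a RIFF file", class = "amtrack_format_error")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_amtrack(path, ": not a WAVE file", class = "amtrack_format_error")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format     = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate       = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        block      = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits       = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_amtrack(path, ": missing fmt or data chunk", class = "amtrack_format_error")

  if (fmt$format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                    endian = "little", signed = TRUE) / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                    endian = "little")
  } else {
    stop_amtrack(path, ": unsupported WAV format (code ", fmt$format, ", ",
                 fmt$bits, " bit); only 16-bit PCM and 32-bit float are read",
                 class = "amtrack_format_error")
  }
  if (fmt$channels == 1L) {
    audio_track(vals, fmt$rate)
  } else {
    m <- matrix(vals, ncol = fmt$channels, byrow = TRUE)
    attr(m, "rate") <- fmt$rate
    m
  }
}

#' Write a WAV file
#'
#' @param x An [audio_track()], numeric vector, or samples-by-channels matrix.
#' @param path Output path.
#' @param rate Sampling rate in Hz; taken from `x` when it is an
#'   `audio_track` or carries a `rate` attribute.
#' @param format `"float32"` (default; exact round-trip of unit-RMS signals)
#'   or `"pcm16"` (values clipped to [-1, 1] and quantized).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "audio_track")) {
    rate <- x$rate
    m <- matrix(x$samples, ncol = 1)
  } else if (is.matrix(x)) {
    rate <- rate %||% attr(x, "rate")
    m <- x
  } else {
    m <- matrix(as.numeric(x), ncol = 1)
  }
  if (is.null(rate)) stop_amtrack("sampling rate unknown", class = "amtrack_spec_error")
  n_ch <- ncol(m)
  interleaved <- as.numeric(t(m))
  bytes_per <- if (format == "float32") 4L else 2L
  data_size <- length(interleaved) * bytes_per
  fact <- format == "float32"

  con <- file(path, "wb")
  on.exit(close(con))
  riff_size <- 4L + (8L + 16L) + (if (fact) 8L + 4L else 0L) + (8L + data_size)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * n_ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  if (fact) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(nrow(m)), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round_half_away(pmax(-1, pmin(1, interleaved)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}
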