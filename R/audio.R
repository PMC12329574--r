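#' Sampled audio buffer
#'
#' A minimal container for mono audio: a numeric vector of linear,
#' dimensionless sample amplitudes plus a sampling rate in Hz.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, rate) {
  stopifnot(is.numeric(samples), is.numeric(rate), length(rate) == 1L, rate > 0)
  if (length(samples) == 0L) stop("empty audio buffer")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("audio_buffer: %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              audio_rms(x)))
  invisible(x)
}

#' @export
length.audio_buffer <- function(x) length(x$samples)

#' Root-mean-square amplitude of a buffer
#' @param audio An [audio_buffer()].
#' @return RMS amplitude (linear units).
#' @export
audio_rms <- function(audio) {
  stopifnot(inherits(audio, "audio_buffer"))
  sqrt(mean(audio$samples^2))
}

#' Convert a dBFS level to linear amplitude
#'
#' Full scale (0 dBFS) corresponds to linear amplitude 1. The default
#' normalization target of the vocoder pipeline is -20 dBFS.
#'
#' @param db Level in dB relative to full scale.
#' @return Linear amplitude.
#' @export
dbfs_to_amp <- function(db) 10^(db / 20)

#' Normalize a buffer to a target RMS amplitude
#'
#' Scales the waveform by a single factor so that its RMS equals
#' `target_rms`; the waveform shape is preserved exactly. Used to equate
#' the level of vocoded stimuli across band counts.
#'
#' @param audio An [audio_buffer()].
#' @param target_rms Target RMS in linear units (default -20 dBFS).
#' @return A rescaled [audio_buffer()].
#' @export
rms_normalize <- function(audio, target_rms = dbfs_to_amp(-20)) {
  stopifnot(inherits(audio, "audio_buffer"),
            is.numeric(target_rms), length(target_rms) == 1L, target_rms > 0)
  r <- audio_rms(audio)
  if (r == 0) stop("cannot normalize an all-zero buffer")
  audio_buffer(audio$samples * (target_rms / r), audio$rate)
}

# --- WAV I/O ------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer for mono PCM 16-bit and IEEE
# float32 files, the two encodings the vocoder pipeline exchanges.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM 16-bit (format tag 1) and IEEE float32
#' (format tag 3), single channel. PCM samples are scaled to [-1, 1).
#'
#' @param path Path to a WAV file.
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  tag <- function() rawToChar(readBin(con, "raw", 4L))
  if (tag() != "RIFF") stop("not a RIFF file: ", path)
  u32()
  if (tag() != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) stop("no data chunk found in ", path)
    sz <- u32()
    cid <- rawToChar(id)
    if (cid == "fmt ") {
      fmt <- list(audio_format = u16(), n_channels = u16(),
                  sample_rate = u32())
      u32(); u16()                       # byte rate, block align
      fmt$bits <- u16()
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (cid == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      if (fmt$n_channels != 1L) stop("only mono WAV files are supported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        x <- readBin(con, "integer", n, size = 2L, endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        x <- readBin(con, "double", n, size = 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      return(audio_buffer(x, fmt$sample_rate))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip chunk (padded to even)
    }
  }
}

#' Write a mono WAV file
#'
#' @param audio An [audio_buffer()].
#' @param path Output path.
#' @param format `"pcm16"` (samples clipped to [-1, 1)) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(audio, "audio_buffer"))
  format <- match.arg(format)
  n <- length(audio$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (format == "pcm16") 1L else 3L)   # format tag
  w16(1L)                                  # mono
  w32(round(audio$rate))
  w32(round(audio$rate) * bytes_per)       # byte rate
  w16(bytes_per)                           # block align
  w16(bytes_per * 8L)                      # bits per sample
  writeChar("data", con, eos = NULL); w32(data_size)
  if (format == "pcm16") {
    x <- pmin(pmax(audio$samples, -1), 32767 / 32768)
    w16(round(x * 32768))
  } else {
    writeBin(audio$samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}
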