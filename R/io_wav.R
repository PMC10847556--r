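#' Read a mono PCM16 WAV file
#'
#' Decodes a RIFF/WAVE file containing a single monophonic channel of
#' 16-bit PCM samples. Samples are returned as reals in \[-1, 1\] obtained
#' by dividing the signed 16-bit integers by 32768.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \[-1,1\]) and
#'   `sample_rate_hz` (integer, from the file header).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt_seen <- FALSE
  n_channels <- NA_integer_; sample_rate <- NA_integer_
  bits <- NA_integer_; audio_format <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      n_channels   <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      sample_rate  <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
      fmt_seen <- TRUE
    } else if (identical(id, "data")) {
      if (!fmt_seen) stop("malformed WAV: data chunk before fmt chunk in ", path)
      if (audio_format != 1L) stop("unsupported WAV encoding (not PCM): format tag ", audio_format)
      if (bits != 16L) stop("unsupported bit depth: ", bits, " (need 16-bit PCM)")
      if (n_channels != 1L) stop("unsupported channel count: ", n_channels, " (need mono)")
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
      if (length(samples) < n) stop("truncated WAV data chunk in ", path)
      break
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples / 32768, sample_rate_hz = sample_rate)
}

#' Write a mono PCM16 WAV file
#'
#' @param samples Numeric vector; values are clipped to \[-1, 1\] and
#'   quantized to signed 16-bit integers.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                     # PCM
  writeBin(1L, con, size = 2, endian = "little")                     # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
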