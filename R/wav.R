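# Minimal RIFF/WAVE I/O for mono recordings. Only what the pipeline needs:
# 16/24-bit integer and 32-bit float PCM, mono; stereo is rejected.

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]` (clipped).
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  check_positive(sample_rate, "sample_rate")
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16- and 24-bit integer PCM and 32-bit IEEE float, mono only;
#' stereo files are rejected with an informative error.
#'
#' @param path WAV file path.
#' @return a list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop_invalid("'%s' is not a RIFF file", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop_invalid("'%s' is not a WAVE file", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      stop_invalid("'%s': no data chunk found", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", size = 2, endian = "little",
                       signed = FALSE),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little"))
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop_invalid("'%s': data before fmt chunk", path)
      if (fmt$channels != 1)
        stop_invalid("'%s' has %d channels; only mono is supported",
                     path, fmt$channels)
      samples <- decode_wav_samples(con, sz, fmt, path)
      return(list(samples = samples, sample_rate = fmt$rate))
    } else {
      readBin(con, "raw", n = sz + sz %% 2)
    }
  }
}

decode_wav_samples <- function(con, sz, fmt, path) {
  if (fmt$code == 1 && fmt$bits == 16) {
    readBin(con, "integer", n = sz %/% 2, size = 2, endian = "little") / 32768
  } else if (fmt$code == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(readBin(con, "raw", n = sz - sz %% 3)), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else if (fmt$code == 3 && fmt$bits == 32) {
    readBin(con, "double", n = sz %/% 4, size = 4, endian = "little")
  } else {
    stop_invalid("'%s': unsupported WAV format (code %d, %d-bit)",
                 path, fmt$code, fmt$bits)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
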