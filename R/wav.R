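# Minimal mono 16-bit PCM WAV I/O. RIFF layout written by hand; no audio
# package is required by the rest of the package.

#' Write a waveform to a WAV file
#'
#' 16-bit PCM, mono. Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param wave Numeric samples in \[-1, 1\] (a `waveform` or plain vector).
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz; defaults to the waveform's
#'   `sample_rate` attribute, falling back to 22050.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = NULL) {
  if (is.null(sample_rate))
    sample_rate <- attr(wave, "sample_rate") %||% 22050
  x <- pmin(pmax(as.numeric(wave), -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File path.
#' @return A `waveform`: numeric samples in \[-1, 1\] with a `sample_rate`
#'   attribute.
#' @export
read_wav <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  sample_rate <- NULL
  repeat {
    chunk_id <- readChar(con, 4)
    if (length(chunk_id) == 0 || nchar(chunk_id) < 4)
      stop("malformed WAV: missing data chunk")
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit PCM WAV is supported")
      if (chunk_size > 16) readBin(con, "raw", chunk_size - 16)
    } else if (identical(chunk_id, "data")) {
      pcm <- readBin(con, "integer", chunk_size / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(structure(pcm / 32767, sample_rate = sample_rate,
                       class = "waveform"))
    } else {
      readBin(con, "raw", chunk_size)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
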