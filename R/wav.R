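# Minimal RIFF/WAVE I/O (mono, 16-bit PCM or 32-bit IEEE float). Written by
# hand because the package only needs single-channel read/write of the two
# canonical encodings.

#' Write a mono WAV file
#'
#' @param samples Numeric vector in [-1, 1] (clipped for 16-bit PCM).
#' @param sampleRate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, sampleRate, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L), all(is.finite(samples)))
  n <- length(samples)
  bytes <- bits %/% 8L
  fmt <- if (bits == 16L) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n * bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")  # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [writeWav()]
#'
#' Supports mono PCM16 and float32 encodings.
#'
#' @param path Input path.
#' @return List with `samples` (numeric) and `sampleRate` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", n = sz)
      le <- function(i, b) sum(as.integer(raw[i:(i + b - 1L)]) * 256^(0:(b - 1L)))
      fmt <- list(code = le(1, 2), channels = le(3, 2), rate = le(5, 4), bits = le(15, 2))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported")
      if (fmt$code == 1L && fmt$bits == 16L) {
        x <- readBin(con, integer(), n = sz %/% 2L, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        x <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      } else stop("unsupported WAV encoding (code ", fmt$code, ", ", fmt$bits, " bits)")
      return(list(samples = x, sampleRate = fmt$rate))
    } else {
      readBin(con, "raw", n = sz + (sz %% 2L))
    }
  }
}
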