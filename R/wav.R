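# Minimal RIFF WAV input/output (16-bit PCM and 32-bit float), enough to
# exchange mono/stereo sounds with standard audio tools.

#' Read a RIFF WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float encodings; samples are
#' returned in [-1, 1]. Multichannel files are kept as a matrix (one
#' column per channel); use \code{\link{loadSound}} for the analysis-ready
#' mono 44.1 kHz form.
#'
#' @param path file path.
#' @return list with \code{samples} (vector or matrix), \code{fs},
#'   \code{bits} and \code{format}.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", 1, 2, endian = "little",
                       signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk: ", path)
  if (fmt$code == 1 && fmt$bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, endian = "little") /
      32768
  } else if (fmt$code == 3 && fmt$bits == 32) {
    x <- readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding: format code %d, %d bits",
                 fmt$code, fmt$bits))
  }
  if (fmt$channels > 1)
    x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  list(samples = x, fs = fmt$fs, bits = fmt$bits,
       format = if (fmt$code == 1) "pcm" else "float")
}

#' Write a waveform to a RIFF WAV file
#'
#' @param w a \linkS4class{Waveform} (samples are clipped to [-1, 1] for
#'   PCM output).
#' @param path output file path.
#' @param format "pcm16" or "float32".
#' @return the path, invisibly.
#' @export
writeWav <- function(w, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- samples(w)
  fs <- as.integer(round(sampleRate(w)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bytes <- 2L; code <- 1L
    pay <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  } else {
    bytes <- 4L; code <- 3L
    pay <- x
  }
  n <- length(pay) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(8L * bytes, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n), con, 4, endian = "little")
  if (format == "pcm16") writeBin(pay, con, 2, endian = "little")
  else writeBin(pay, con, 4, endian = "little")
  invisible(path)
}
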