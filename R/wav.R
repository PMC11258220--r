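# Minimal mono WAV I/O (16-bit PCM and 32-bit IEEE float). Kept in-package
# because no installed package reads audio; covers only what the stimulus
# module needs: single-channel RIFF/WAVE files.

#' Write a mono WAV file
#'
#' @param x a [token_wave()], [concatenate_stream()] result, or numeric
#'   vector of samples in \[-1, 1\].
#' @param path output file path.
#' @param fs sampling rate; taken from `x` when it is a package object.
#' @param format `"pcm16"` (16-bit integer) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (inherits(x, "token_wave")) { fs <- x$fs_audio; x <- x$samples }
  else if (inherits(x, "stimulus_stream")) { fs <- x$fs_audio; x <- x$samples }
  if (is.null(fs)) stop("fs must be given for a bare sample vector",
                        call. = FALSE)
  n <- length(x)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2,
           endian = "little")                       # audio format tag
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, single channel.
#'
#' @param path input file path.
#' @return A [token_wave()] with the file's samples and rate.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      tag <- readBin(con, "integer", 1, 2, endian = "little")
      nchan <- readBin(con, "integer", 1, 2, endian = "little")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
      if (nchan != 1L) stop("only mono WAV supported", call. = FALSE)
      fmt <- list(tag = tag, fs = fs, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$tag == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size %/% 2L, 2,
                           endian = "little", signed = TRUE) / 32767
      } else if (fmt$tag == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size %/% 4L, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (tag ", fmt$tag, ", ", fmt$bits,
             " bits)", call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  token_wave(samples, fmt$fs)
}
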