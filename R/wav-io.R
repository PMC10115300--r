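#' Read a mono PCM WAV file
#'
#' Reads an integer PCM (RIFF/WAVE) file and returns samples normalized to
#' `[-1, 1)`, dividing by `2^(bits - 1)`. Only single-channel integer PCM
#' (16, 24 or 32 bit) is supported; float or multichannel files raise an
#' error rather than being silently mis-scaled.
#'
#' @param path path to a `.wav` file.
#' @return list with `samples` (numeric vector in `[-1, 1)`), `sample_rate`
#'   (Hz), and `bits` (bits per sample).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)
  if (fmt$audio_format != 1L)
    stop("unsupported WAV format ", fmt$audio_format,
         " (only integer PCM is supported): ", path)
  if (fmt$channels != 1L)
    stop("unsupported channel count ", fmt$channels,
         " (only mono is supported): ", path)

  samples <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                   endian = "little") / 2^15,
    "32" = readBin(data_raw, "integer", length(data_raw) / 4L, size = 4,
                   endian = "little") / 2^31,
    "24" = pcm24_to_numeric(data_raw),
    stop("unsupported bit depth ", fmt$bits, ": ", path)
  )
  list(samples = as.numeric(samples), sample_rate = fmt$sample_rate,
       bits = fmt$bits)
}

pcm24_to_numeric <- function(raw) {
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
  x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
  x <- ifelse(x >= 2^23, x - 2^24, x)
  x / 2^23
}

#' Write a mono PCM WAV file
#'
#' Inverse of [read_wav()]: quantizes normalized samples to integer PCM and
#' writes a canonical 44-byte-header RIFF/WAVE file. Samples outside
#' `[-1, 1)` are hard-clipped at full scale (mirroring a fixed-gain
#' recorder); round-tripping in-range samples reproduces them to 1 LSB.
#'
#' @param samples numeric vector in `[-1, 1)`.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bits bits per sample, one of 16, 24, 32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L, 32L)) stop("bits must be 16, 24 or 32")
  full <- 2^(bits - 1)
  q <- as.integer(pmax(pmin(round(samples * full), full - 1), -full))

  bytes_per <- bits %/% 8L
  data_size <- length(q) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 24L) {
    x <- ifelse(q < 0, q + 2^24, q)
    b <- rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(q, con, size = bytes_per, endian = "little")
  }
  invisible(path)
}
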