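# Minimal RIFF/WAVE I/O for mono or multichannel PCM16/24 and float32
# files; only what the stimulus pipeline needs.

#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float32. Multichannel files are averaged
#' to mono (the pipeline is single-channel).
#'
#' @param path File path.
#' @return An `audio_track` with samples scaled to \[-1, 1\] for PCM.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file", call. = FALSE)
  x <- if (fmt$format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2,
            endian = "little") / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    n <- length(data_raw) / 3
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v[seq_len(n)] / 8388608
  } else if (fmt$format == 3 && fmt$bits == 32) {
    readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$format, fmt$bits), call. = FALSE)
  }
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_track(x, fmt$rate)
}

#' Write a WAV file
#'
#' @param audio An `audio_track`; samples are clipped to \[-1, 1\] for PCM.
#' @param path Destination path.
#' @param bits `16` (PCM) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "audio_track"))
  x <- audio$samples
  rate <- as.integer(round(audio$rate))
  float <- identical(bits, "float32")
  bps <- if (float) 32L else 16L
  data_size <- length(x) * (bps / 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (float) 3L else 1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(rate, con, 4, endian = "little")
  writeBin(as.integer(rate * bps / 8), con, 4, endian = "little")
  writeBin(as.integer(bps / 8), con, 2, endian = "little")
  writeBin(bps, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (float) {
    writeBin(x, con, 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmin(pmax(x, -1), 1) * 32767)), con, 2,
             endian = "little")
  }
  invisible(path)
}
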