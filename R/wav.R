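# Minimal RIFF/WAVE codec over base readBin/writeBin. Integer PCM is
# scaled by 2^(bits-1) so full-scale negative maps to -1.0 and +32767
# (16-bit) to 32767/32768; 8-bit PCM is the unsigned-offset convention.

read_u32 <- function(con) readBin(con, "integer", 1, size = 4, endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1, size = 2, endian = "little",
                                  signed = FALSE)

#' Read a WAV file
#'
#' Supports PCM 8/16/24/32-bit and IEEE float32, mono or multichannel
#' (one channel is selected). Integer samples are scaled to \[-1, 1\] by
#' the type's half range; the sampling rate comes from the header.
#'
#' @param path path to a RIFF/WAVE file.
#' @param channel 1-based channel to extract for multichannel files
#'   (default 1).
#' @return A [pcg_signal()].
#' @export
read_wav <- function(path, channel = 1L) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(rawToChar(readBin(con, "raw", 4)), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  invisible(read_u32(con))
  if (!identical(rawToChar(readBin(con, "raw", 4)), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    sz <- read_u32(con)
    if (id == "fmt ") {
      fmt <- list(audio_format = read_u16(con),
                  n_channels = read_u16(con),
                  sample_rate = read_u32(con))
      invisible(read_u32(con))  # byte rate
      invisible(read_u16(con))  # block align
      fmt$bits <- read_u16(con)
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in WAV file", call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0)
    stop("zero-length audio data in WAV file", call. = FALSE)
  bytes <- fmt$bits %/% 8L
  x <- if (fmt$audio_format == 1L) {
    switch(as.character(fmt$bits),
      "8" = (as.numeric(readBin(data_raw, "integer",
               length(data_raw), size = 1, signed = FALSE)) - 128) / 128,
      "16" = as.numeric(readBin(data_raw, "integer",
               length(data_raw) %/% 2L, size = 2, endian = "little")) / 32768,
      "24" = {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = as.numeric(readBin(data_raw, "integer",
               length(data_raw) %/% 4L, size = 4, endian = "little")) / 2147483648,
      stop(sprintf("unsupported PCM bit depth: %d", fmt$bits), call. = FALSE))
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) %/% 4L, size = 4,
            endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding: format %d, %d bits",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  nc <- fmt$n_channels
  if (nc > 1L) {
    channel <- as.integer(channel)
    if (channel < 1L || channel > nc)
      stop(sprintf("channel %d requested but file has %d channels",
                   channel, nc), call. = FALSE)
    x <- x[seq(channel, length(x), by = nc)]
  }
  pcg_signal(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' Writes a mono RIFF/WAVE file at the signal's sampling rate. Samples
#' must lie in \[-1, 1\] unless `clip = TRUE`, in which case they are
#' hard clipped.
#'
#' @param signal a [pcg_signal()].
#' @param path output file path.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @param clip allow clipping of out-of-range samples (default FALSE).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, encoding = c("pcm16", "float32"),
                      clip = FALSE) {
  stop_if_not_signal(signal)
  encoding <- match.arg(encoding)
  x <- signal$samples
  peak <- max(abs(x))
  if (peak > 1) {
    if (!clip)
      stop(sprintf("samples exceed [-1, 1] (peak %.6g); rescale or set clip = TRUE",
                   peak), call. = FALSE)
    x <- pmin(pmax(x, -1), 1)
  }
  n <- length(x)
  fs <- as.integer(round(signal$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  if (encoding == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    data_size <- 2L * n
  } else {
    fmt_code <- 3L; bits <- 32L
    data_size <- 4L * n
  }
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(fmt_code); w16(1L)  # mono
  w32(fs)
  w32(fs * (bits %/% 8L))
  w16(bits %/% 8L); w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (encoding == "pcm16") {
    q <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
    w16(q)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
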