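#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the two encodings the toolkit writes and
#' consumes: 16-bit integer PCM (scaled to [-1, 1)) and 32-bit IEEE
#' float (read exactly). Multichannel files and other encodings are
#' rejected.
#'
#' @param path Path to a WAV file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L)
        stop(sprintf("only mono WAV supported (file has %d channels)", fmt$channels))
      if (fmt$code == 1L && fmt$bits == 16L) {
        v <- readBin(con, "integer", sz / 2, 2, signed = TRUE, endian = "little")
        samples <- v / 32768
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bits); need PCM16 or float32",
                     fmt$code, fmt$bits))
      }
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  waveform(samples, fmt$sample_rate)
}

#' Write a waveform to a mono WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param format `"float32"` (default; read-back is bit-identical) or
#'   `"pcm16"` (samples must lie within [-1, 1]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("float32", "pcm16")) {
  stopifnot_waveform(w)
  format <- match.arg(format)
  n <- length(w$samples)
  sr <- round(w$sample_rate)
  bytes_per <- if (format == "float32") 4L else 2L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  code <- if (format == "float32") 3L else 1L
  writeBin(code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(w$samples, con, 4, endian = "little")
  } else {
    if (max(abs(w$samples)) > 1)
      stop("pcm16 output requires samples within [-1, 1]; rescale first")
    v <- as.integer(pmax(pmin(round(w$samples * 32767), 32767L), -32768L))
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}
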