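# Minimal RIFF/WAVE PCM I/O. Only uncompressed 16-bit PCM is supported,
# which is what the field's digital audio recorders write; anything else is
# rejected with an explicit error naming the file.

#' Read a WAV file
#'
#' Reads an uncompressed 16-bit PCM RIFF/WAVE file. Amplitudes are scaled to
#' [-1, 1] by dividing the signed 16-bit integers by 32767, the exact
#' inverse of [writeWav()]'s quantization, so a write/read round trip is
#' bit-identical. Multi-channel files use the first channel only, with a
#' warning.
#'
#' @param path path to a .wav file.
#' @return A [Waveform-class].
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fileSize <- file.size(path)
  readTag <- function() rawToChar(readBin(con, "raw", 4L))
  if (fileSize < 12L || readTag() != "RIFF")
    stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # declared RIFF size
  if (readTag() != "WAVE") stop("not a WAVE file: ", path)

  fmt <- NULL
  smp <- NULL
  pos <- 12L
  while (pos + 8L <= fileSize) {
    tag <- readTag()
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    pos <- pos + 8L
    if (pos + size > fileSize)
      stop(sprintf("truncated WAV file %s: chunk '%s' claims %d bytes at offset %d but file has %d",
                   path, tag, size, pos, fileSize))
    if (tag == "fmt ") {
      audioFormat <- readBin(con, "integer", 1L, 2L, endian = "little")
      nChannels <- readBin(con, "integer", 1L, 2L, endian = "little")
      rate <- readBin(con, "integer", 1L, 4L, endian = "little")
      readBin(con, "integer", 1L, 4L, endian = "little")  # byte rate
      readBin(con, "integer", 1L, 2L, endian = "little")  # block align
      bits <- readBin(con, "integer", 1L, 2L, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
      fmt <- list(format = audioFormat, channels = nChannels, rate = rate,
                  bits = bits)
    } else if (tag == "data") {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$format != 1L || fmt$bits != 16L)
        stop(sprintf("unsupported WAV encoding in %s: format %d, %d-bit (only 16-bit PCM is supported)",
                     path, fmt$format, fmt$bits))
      n <- size %/% 2L
      smp <- readBin(con, "integer", n, 2L, signed = TRUE, endian = "little")
      if (length(smp) < n)
        stop(sprintf("truncated WAV file %s: expected %d samples at offset %d, read %d",
                     path, n, pos, length(smp)))
      if (size %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (padded)
    }
    pos <- pos + size + size %% 2L
  }
  if (is.null(fmt) || is.null(smp))
    stop("no fmt/data chunks found in WAV file: ", path)
  if (fmt$channels > 1L) {
    warning(sprintf("%s has %d channels; using the first channel only",
                    path, fmt$channels))
    smp <- smp[seq(1L, length(smp), by = fmt$channels)]
  }
  waveform(smp / 32767, fmt$rate)
}

#' Write a Waveform as a mono 16-bit PCM WAV file
#'
#' Samples are quantized as `round(x * 32767)`, clamped to the 16-bit range
#' (with a warning if any sample exceeded full scale).
#'
#' @param w a [Waveform-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  q <- round(w@samples * 32767)
  if (any(q > 32767 | q < -32768)) {
    warning("samples exceed full scale; clipping to [-1, 1]")
    q <- pmin(pmax(q, -32768), 32767)
  }
  q <- as.integer(q)
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                      # PCM
  writeBin(1L, con, 2L, endian = "little")                      # mono
  writeBin(as.integer(w@sampleRate), con, 4L, endian = "little")
  writeBin(as.integer(w@sampleRate * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")                      # block align
  writeBin(16L, con, 2L, endian = "little")                     # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4L, endian = "little")
  writeBin(q, con, 2L, endian = "little")
  invisible(path)
}

#' Select a random analysis window from a recording
#'
#' Analysis operates on a 77- to 300-s sample selected at random from each
#' recording. The segment length is uniform in `[minLen, min(maxLen,
#' recording length)]` and its start uniform over feasible positions;
#' selection is deterministic given `rngSeed`. Recordings shorter than
#' `minLen` are returned whole with a warning so that short test fixtures
#' remain usable.
#'
#' @param w a [Waveform-class].
#' @param minLen,maxLen window bounds in seconds (defaults 77 and 300).
#' @param rngSeed integer seed.
#' @return A [Waveform-class] segment of `w`.
#' @export
selectAnalysisWindow <- function(w, minLen = 77, maxLen = 300, rngSeed = 1L) {
  stopifnot(is(w, "Waveform"), minLen > 0, maxLen >= minLen)
  total <- duration(w)
  if (total < minLen) {
    warning(sprintf(
      "recording is %.1f s, shorter than the %.0f s minimum window; analyzing it whole",
      total, minLen))
    return(w)
  }
  withSeed(rngSeed, {
    len <- stats::runif(1, minLen, min(maxLen, total))
    start <- stats::runif(1, 0, total - len)
    i0 <- durationToSamples(start, w@sampleRate) + 1L
    i1 <- min(i0 + durationToSamples(len, w@sampleRate) - 1L, length(w))
    waveform(w@samples[i0:i1], w@sampleRate)
  })
}
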