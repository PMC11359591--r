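#' Construct an audio segment
#'
#' The basic container for a mono audio signal: a numeric sample vector in
#' `[-1, 1]`, its sampling rate in Hz, an optional class label and a
#' provenance string.  All analysis functions in the package consume and
#' produce this type.
#'
#' @param samples Numeric vector of amplitudes, expected in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param label One of `"worker"`, `"drone"`, `"unknown"`.
#' @param source_id Provenance string (file name, generator tag, ...).
#' @return An object of class `bee_audio`.
#' @export
bee_audio <- function(samples, sample_rate, label = "unknown", source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) > 0 && !all(is.finite(samples))) {
    stop_arg("audio samples must all be finite")
  }
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate <= 0) {
    stop_arg("sample_rate must be a positive integer")
  }
  label <- match.arg(label, c("worker", "drone", "unknown"))
  structure(
    list(samples = samples, sample_rate = sample_rate,
         label = label, source_id = as.character(source_id)),
    class = "bee_audio"
  )
}

#' @export
print.bee_audio <- function(x, ...) {
  cat(sprintf("<bee_audio> %.3f s @ %d Hz, label=%s, source=%s\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              x$label, x$source_id))
  invisible(x)
}

#' @export
length.bee_audio <- function(x) length(x$samples)

#' Read a 16-bit PCM WAV file
#'
#' Reads an uncompressed RIFF/WAVE file, converts the 16-bit integer samples
#' to real values in `[-1, 1]` by division by 32768, and mixes multichannel
#' input down to mono by averaging the channels.  If `target_rate` is given
#' and differs from the file's rate, the signal is resampled by rational
#' polyphase resampling so downstream frequency-bin mappings stay fixed.
#'
#' @param path Path to a WAV file.
#' @param label Optional class label to attach (`"worker"`, `"drone"`,
#'   `"unknown"`).
#' @param target_rate If non-`NULL`, resample to this rate in Hz.
#' @return A [bee_audio] object; `source_id` is the file's base name.
#' @export
read_wav <- function(path, label = "unknown", target_rate = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (file.size(path) == 0) stop_arg("empty WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_arg("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_arg("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format    = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate      = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block     = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits      = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      # skip unknown chunk (word aligned)
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_arg("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$format != 1L) stop_arg("unsupported WAV codec (only 16-bit PCM): format tag ", fmt$format)
  if (fmt$bits != 16L) stop_arg("unsupported bit depth (only 16-bit PCM): ", fmt$bits, " bits")
  if (length(data_raw) == 0) stop_arg("WAV file has no audio data: ", path)

  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2,
                  size = 2, endian = "little", signed = TRUE)
  x <- ints / 32768
  if (fmt$channels > 1L) {
    nfrm <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfrm * fmt$channels)], nrow = fmt$channels))
  }
  out <- bee_audio(x, fmt$rate, label = label, source_id = basename(path))
  if (!is.null(target_rate) && fmt$rate != target_rate) {
    out <- resample_audio(out, target_rate)
  }
  out
}

#' Write a 16-bit PCM WAV file
#'
#' Quantizes the samples to 16-bit integers and writes a mono RIFF/WAVE
#' file.  A read/write round trip reproduces the signal within one
#' quantization step (1/32768).
#'
#' @param segment A [bee_audio] object with samples in `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path) {
  stopifnot(inherits(segment, "bee_audio"))
  x <- segment$samples
  if (length(x) > 0 && max(abs(x)) > 1 + 1e-9) {
    stop_arg("samples exceed [-1, 1]; normalize before writing")
  }
  ints <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_bytes <- length(ints) * 2L
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop_arg("cannot open for writing: ", path)
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                      # PCM
  writeBin(1L, con, size = 2, endian = "little")                      # mono
  writeBin(segment$sample_rate, con, size = 4, endian = "little")
  writeBin(segment$sample_rate * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")                      # block align
  writeBin(16L, con, size = 2, endian = "little")                     # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample audio to a new rate
#'
#' Rational polyphase resampling (via [signal::resample]) to `target_rate`.
#'
#' @param audio A [bee_audio] object.
#' @param target_rate New sampling rate in Hz.
#' @return A [bee_audio] object at `target_rate`.
#' @export
resample_audio <- function(audio, target_rate) {
  stopifnot(inherits(audio, "bee_audio"))
  target_rate <- as.integer(target_rate)
  if (target_rate == audio$sample_rate) return(audio)
  g <- gcd(target_rate, audio$sample_rate)
  y <- signal::resample(audio$samples, p = target_rate %/% g, q = audio$sample_rate %/% g)
  y <- pmax(-1, pmin(1, y))
  bee_audio(y, target_rate, label = audio$label, source_id = audio$source_id)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Cut audio into fixed-length segments
#'
#' Splits a recording into consecutive non-overlapping windows of
#' `round(duration_s * sample_rate)` samples.  A trailing remainder shorter
#' than one window is discarded; the label and source id propagate to every
#' segment.
#'
#' @param audio A [bee_audio] object.
#' @param duration_s Window length in seconds (default 1, the analysis
#'   granularity used throughout the package).
#' @return A list of [bee_audio] segments (possibly empty).
#' @export
segment_audio <- function(audio, duration_s = 1) {
  stopifnot(inherits(audio, "bee_audio"))
  if (duration_s <= 0) stop_arg("duration_s must be positive")
  win <- round(duration_s * audio$sample_rate)
  n_seg <- length(audio$samples) %/% win
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * win + 1):(i * win)
    bee_audio(audio$samples[idx], audio$sample_rate, label = audio$label,
              source_id = sprintf("%s#%03d", audio$source_id, i))
  })
}

#' Load a labelled WAV directory tree
#'
#' Reads every `.wav` file under `dir/worker/` and `dir/drone/`, assigns the
#' label from the folder name, resamples to `target_rate` when needed, and
#' cuts each file into `duration_s` segments.
#'
#' @param dir Root directory with `worker/` and `drone/` subfolders.
#' @param duration_s Segment length in seconds.
#' @param target_rate Analysis sampling rate in Hz (default 44100).
#' @return A list of labelled [bee_audio] segments.
#' @export
load_audio_dir <- function(dir, duration_s = 1, target_rate = 44100) {
  if (!dir.exists(dir)) stop_arg("directory not found: ", dir)
  out <- list()
  for (cls in c("worker", "drone")) {
    sub <- file.path(dir, cls)
    if (!dir.exists(sub)) next
    files <- sort(list.files(sub, pattern = "\\.wav$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      a <- read_wav(f, label = cls, target_rate = target_rate)
      out <- c(out, segment_audio(a, duration_s))
    }
  }
  out
}
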