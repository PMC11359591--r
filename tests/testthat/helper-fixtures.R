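# Shared fixtures, all generated in code.

# Pure tone segment (no jitter, no AM, no noise unless asked).
make_tone <- function(freq, duration_s = 0.2, sample_rate = 44100,
                      amplitude = 0.9, snr_db = Inf, seed = 1) {
  n <- round(duration_s * sample_rate)
  t <- (0:(n - 1)) / sample_rate
  x <- amplitude * sin(2 * pi * freq * t)
  if (is.finite(snr_db)) {
    x <- x + withr::with_seed(seed, rnorm(n, sd = sqrt(mean(x^2) / 10^(snr_db / 10))))
  }
  bee_audio(x / max(abs(x)) * amplitude, sample_rate)
}

# Small cepstral config that keeps per-test cost low.
tiny_cepstral <- function(...) {
  cepstral_config(frame_len = 512L, hop = 256L, n_filters = 20L,
                  fmin = 50, fmax = 8000, ...)
}

# Write a raw PCM WAV by hand (independent of write_wav) so the reader can
# be checked against first-principles bytes, including multichannel.
write_raw_wav <- function(path, ints, sample_rate = 44100, channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(ints) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L * channels), con, size = 4, endian = "little")
  writeBin(as.integer(2L * channels), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(as.integer(ints), con, size = 2, endian = "little")
  path
}

gaussian_model <- function(mu, sigma, prior = 0.5) {
  structure(list(mu = mu, sigma = sigma, prior = prior),
            class = "gaussian_class_model")
}
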