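#' Configuration for the cepstral feature extractors
#'
#' Shared framing and filterbank parameters for MFCC and GTCC extraction.
#' Defaults give about 42 Hamming-windowed frames per 1-s segment at
#' 44.1 kHz and a 120-filter bank between 50 Hz and 6 kHz, bracketing the
#' wingbeat fundamental (~260 Hz) and its informative harmonics.  All 120
#' cepstral coefficients are kept (no truncation), so the per-segment
#' feature dimension equals the number of filters.
#'
#' @param frame_len Frame length in samples (default 2048, ~46 ms at
#'   44.1 kHz).
#' @param hop Hop between frame starts in samples (default 1024).
#' @param n_filters Number of filters `M` (default 120).
#' @param n_fft FFT length (default `frame_len`).
#' @param fmin,fmax Filterbank frequency range in Hz.
#' @param n_coeffs Number of cepstral coefficients kept (default
#'   `n_filters`).
#' @param gamma_order Gammatone filter order `N` (default 4).
#' @param erb_model Equivalent-rectangular-bandwidth model for the gammatone
#'   bank; only `"glasberg_moore"` is implemented.
#' @param aggregate Per-segment statistic collapsing the per-frame
#'   coefficient vectors: `"mean"` or `"median"`.
#' @param energy_floor Floor applied to filterbank energies before `log10`.
#' @return A list of class `cepstral_config`.
#' @export
cepstral_config <- function(frame_len = 2048L, hop = 1024L, n_filters = 120L,
                            n_fft = frame_len, fmin = 50, fmax = 6000,
                            n_coeffs = n_filters, gamma_order = 4L,
                            erb_model = c("glasberg_moore"),
                            aggregate = c("mean", "median"),
                            energy_floor = 1e-12) {
  erb_model <- match.arg(erb_model)
  aggregate <- match.arg(aggregate)
  if (hop > frame_len) stop_arg("hop must not exceed frame_len")
  if (n_coeffs > n_filters) stop_arg("n_coeffs must not exceed n_filters")
  if (fmin < 0 || fmax <= fmin) stop_arg("need 0 <= fmin < fmax")
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 n_filters = as.integer(n_filters), n_fft = as.integer(n_fft),
                 fmin = fmin, fmax = fmax, n_coeffs = as.integer(n_coeffs),
                 gamma_order = as.integer(gamma_order), erb_model = erb_model,
                 aggregate = aggregate, energy_floor = energy_floor),
            class = "cepstral_config")
}

#' Hertz to mel conversion
#'
#' `mel(f) = 1127 * ln(1 + f/700)`, the natural-log mel map.
#'
#' @param f Frequency in Hz (nonnegative).
#' @return Frequency on the mel scale.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop_arg("frequency must be nonnegative")
  1127 * log(1 + f / 700)
}

#' Mel to hertz conversion (inverse of [hz_to_mel])
#' @param mel Frequency on the mel scale.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(mel) 700 * (exp(mel / 1127) - 1)

#' Triangular mel filterbank
#'
#' `M` unit-peak triangular filters whose center frequencies are equally
#' spaced on the mel scale between `mel(fmin)` and `mel(fmax)`; each filter
#' rises from the previous center and falls to zero at the next, so adjacent
#' filters overlap up to each other's centers.  Weights are evaluated at the
#' one-sided FFT bin frequencies.
#'
#' @param config A [cepstral_config].
#' @param sample_rate Sampling rate in Hz.
#' @return An `M x (n_fft/2 + 1)` nonnegative matrix with attribute
#'   `center_hz`.
#' @export
mel_filterbank <- function(config, sample_rate = 44100) {
  if (config$fmax > sample_rate / 2) stop_arg("fmax exceeds the Nyquist frequency")
  M <- config$n_filters
  n_bins <- config$n_fft %/% 2L + 1L
  bin_hz <- (0:(n_bins - 1)) * sample_rate / config$n_fft
  pts_mel <- seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
                 length.out = M + 2L)
  pts_hz <- mel_to_hz(pts_mel)
  W <- matrix(0, M, n_bins)
  for (m in seq_len(M)) {
    lo <- pts_hz[m]; c0 <- pts_hz[m + 1]; hi <- pts_hz[m + 2]
    up <- (bin_hz - lo) / (c0 - lo)
    down <- (hi - bin_hz) / (hi - c0)
    W[m, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(W) == 0)) {
    stop_arg("filterbank too dense for the FFT grid: some filters have no ",
             "nonzero bin; reduce n_filters or increase n_fft")
  }
  structure(W, center_hz = pts_hz[2:(M + 1)])
}

#' Gammatone filter frequency response
#'
#' `GT(f) = (1 + i (f - f0)/BW)^(-N)`: unit gain at the center frequency,
#' magnitude symmetric about it, and -3.01 dB one bandwidth away when
#' `N = 1`.
#'
#' @param f Frequency in Hz (vectorized).
#' @param f0 Center frequency in Hz.
#' @param bw Bandwidth in Hz (positive).
#' @param order Filter order `N` (>= 1).
#' @return Complex response values.
#' @export
gammatone_response <- function(f, f0, bw, order = 4L) {
  if (bw <= 0) stop_arg("bandwidth must be positive")
  if (order < 1) stop_arg("order must be >= 1")
  (1 + 1i * (f - f0) / bw)^(-order)
}

# ERB-rate scale (Glasberg & Moore): number of ERBs below frequency f.
hz_to_erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

# Glasberg & Moore equivalent rectangular bandwidth at center frequency f0.
erb_bandwidth <- function(f0) 24.7 * (4.37 * f0 / 1000 + 1)

#' Gammatone filterbank
#'
#' Magnitude-squared gammatone responses sampled on the one-sided FFT grid.
#' Center frequencies are equally spaced on the ERB-rate scale between
#' `fmin` and `fmax`; each filter's bandwidth follows the Glasberg-Moore
#' ERB model `ERB(f0) = 24.7 (4.37 f0/1000 + 1)`.
#'
#' @inheritParams mel_filterbank
#' @return An `M x (n_fft/2 + 1)` nonnegative matrix with attribute
#'   `center_hz`.
#' @export
gammatone_filterbank <- function(config, sample_rate = 44100) {
  if (config$fmax > sample_rate / 2) stop_arg("fmax exceeds the Nyquist frequency")
  M <- config$n_filters
  n_bins <- config$n_fft %/% 2L + 1L
  bin_hz <- (0:(n_bins - 1)) * sample_rate / config$n_fft
  centers <- erb_rate_to_hz(seq(hz_to_erb_rate(config$fmin),
                                hz_to_erb_rate(config$fmax),
                                length.out = M))
  W <- matrix(0, M, n_bins)
  for (m in seq_len(M)) {
    W[m, ] <- Mod(gammatone_response(bin_hz, centers[m],
                                     erb_bandwidth(centers[m]),
                                     config$gamma_order))^2
  }
  structure(W, center_hz = centers)
}

#' Cepstral DCT
#'
#' The discrete cosine transform applied to log filterbank energies:
#' `c_i = sqrt(2/M) * sum_m log10(Y_m) cos((2m - 1) i pi / (2M))` for
#' `i = 1..n_coeffs` (base-10 logarithm).
#'
#' @param log_energies Vector of `log10` filterbank energies (length `M`).
#' @param n_coeffs Number of coefficients returned.
#' @return Numeric vector of length `n_coeffs`.
#' @export
cepstral_dct <- function(log_energies, n_coeffs = length(log_energies)) {
  M <- length(log_energies)
  C <- cos(outer(seq_len(n_coeffs), (2 * seq_len(M) - 1) * pi / (2 * M)))
  sqrt(2 / M) * as.numeric(C %*% log_energies)
}

# Hamming-windowed power spectra of all frames: (n_fft/2+1) x n_frames.
frame_power_spectra <- function(samples, config) {
  n <- length(samples)
  fl <- config$frame_len
  if (n < fl) stop_arg("segment shorter than one analysis frame")
  starts <- seq(1L, n - fl + 1L, by = config$hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(fl - 1)) / (fl - 1))  # Hamming
  n_bins <- config$n_fft %/% 2L + 1L
  P <- matrix(0, n_bins, length(starts))
  pad <- config$n_fft - fl
  for (j in seq_along(starts)) {
    fr <- samples[starts[j]:(starts[j] + fl - 1L)] * w
    if (pad > 0) fr <- c(fr, numeric(pad))
    X <- fft(fr)
    P[, j] <- Mod(X[seq_len(n_bins)])^2
  }
  P
}

cepstral_pipeline <- function(segment, config, filterbank, method) {
  stopifnot(inherits(segment, "bee_audio"))
  P <- frame_power_spectra(segment$samples, config)
  Y <- filterbank %*% P                       # M x n_frames energies
  if (any(colSums(Y) == 0)) {
    warning("silent frame(s): filterbank energies floored before log10")
  }
  Y <- pmax(Y, config$energy_floor)
  cc <- apply(log10(Y), 2, cepstral_dct, n_coeffs = config$n_coeffs)
  cc <- matrix(cc, nrow = config$n_coeffs)    # guard n_coeffs == 1
  v <- switch(config$aggregate,
              mean = rowMeans(cc),
              median = apply(cc, 1, stats::median))
  structure(as.numeric(v), method = method)
}

#' Mel-frequency cepstral coefficients of a segment
#'
#' Per frame: Hamming window, FFT, squared magnitude, triangular mel
#' filterbank energies, `log10`, cepstral DCT.  Per segment: the frames'
#' coefficient vectors are collapsed by the configured aggregate (mean by
#' default).
#'
#' @param segment A [bee_audio] object at least one frame long.
#' @param config A [cepstral_config].
#' @return Numeric vector of length `config$n_coeffs` with attribute
#'   `method = "mfcc"`.
#' @export
mfcc <- function(segment, config = cepstral_config()) {
  fb <- mel_filterbank(config, segment$sample_rate)
  cepstral_pipeline(segment, config, fb, "mfcc")
}

#' Gammatone cepstral coefficients of a segment
#'
#' Identical pipeline to [mfcc] with the triangular mel bank replaced by
#' magnitude-squared gammatone responses on an ERB-spaced grid.
#'
#' @inheritParams mfcc
#' @return Numeric vector of length `config$n_coeffs` with attribute
#'   `method = "gtcc"`.
#' @export
gtcc <- function(segment, config = cepstral_config()) {
  fb <- gammatone_filterbank(config, segment$sample_rate)
  cepstral_pipeline(segment, config, fb, "gtcc")
}
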