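#' Configuration for the spectral feature extractors
#'
#' Parameters of the Burg autoregressive PSD and the MUSIC pseudospectrum.
#' Both estimators return `n_freq_bins` values on a linear one-sided
#' frequency grid over `[0, sample_rate/2)`.
#'
#' @param ar_order Burg AR model order `m`.  32 poles are enough to model
#'   the wingbeat fundamental plus several harmonics below a few kHz while
#'   remaining stable on 1-s frames.
#' @param n_freq_bins Feature dimension (default 512).
#' @param music_matrix_size Dimension `M` of the autocorrelation matrix used
#'   by MUSIC (`M` much smaller than the segment length).  The correlation
#'   window `M / sample_rate` must be on the order of a wingbeat period for
#'   the pseudospectrum to resolve the fundamental region: at 44.1 kHz the
#'   default 128 spans ~2.9 ms, comparable to the ~3.8 ms worker wingbeat
#'   period, whereas smaller matrices blur the two classes together.
#' @param music_signal_dim Signal-subspace dimension `p` (`p < M`); 12
#'   accommodates about six real sinusoids (fundamental plus harmonics)
#'   while keeping a large, stable noise subspace.
#' @param to_db Store features as `10*log10(power)` so the bounded-range
#'   autoencoder sees a compressed dynamic range.  Set `FALSE` for raw power.
#' @param psd_floor Lower clamp applied to the squared AR polynomial modulus
#'   to keep the PSD finite near unit-circle roots.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(ar_order = 32L, n_freq_bins = 512L,
                            music_matrix_size = 128L, music_signal_dim = 12L,
                            to_db = TRUE, psd_floor = 1e-12) {
  if (ar_order < 1) stop_arg("ar_order must be >= 1")
  if (music_signal_dim < 0 || music_signal_dim >= music_matrix_size) {
    stop_arg("music_signal_dim must satisfy 0 <= p < music_matrix_size")
  }
  structure(list(ar_order = as.integer(ar_order),
                 n_freq_bins = as.integer(n_freq_bins),
                 music_matrix_size = as.integer(music_matrix_size),
                 music_signal_dim = as.integer(music_signal_dim),
                 to_db = isTRUE(to_db), psd_floor = psd_floor),
            class = "spectral_config")
}

#' Burg maximum-entropy AR fit
#'
#' Fits an autoregressive model of the given order by the Burg lattice
#' recursion: at each stage the reflection coefficient is chosen to minimize
#' the summed forward and backward prediction-error powers, and the AR
#' coefficients are propagated by the Levinson update.  The segment mean is
#' removed first.  The returned coefficients follow the prediction-polynomial
#' convention `A(z) = 1 + sum_k a_k z^-k`, i.e. an AR(1) process
#' `x(n) = 0.9 x(n-1) + w(n)` yields `a_1` close to -0.9.
#'
#' @param samples Numeric signal vector.
#' @param order AR order `m` (must be `< length(samples)`).
#' @return A list with `ar` (coefficients `a_1..a_m`), `noise_power` (the
#'   final prediction-error power `E_m`), and `reflection` (per-stage
#'   reflection coefficients, all with magnitude `<= 1`).
#' @export
burg_fit <- function(samples, order) {
  x <- as.numeric(samples)
  n <- length(x)
  order <- as.integer(order)
  if (order < 1) stop_arg("order must be >= 1")
  if (order >= n) stop_arg("order must be smaller than the signal length")
  x <- x - mean(x)
  e0 <- sum(x^2) / n
  if (e0 <= .Machine$double.eps) {
    stop_arg("degenerate signal: zero variance after mean removal")
  }
  f <- x
  b <- x
  a <- numeric(0)
  refl <- numeric(order)
  E <- e0
  for (m in seq_len(order)) {
    fm <- f[-1L]
    bm <- b[-length(b)]
    den <- sum(fm * fm) + sum(bm * bm)
    k <- if (den > 0) -2 * sum(fm * bm) / den else 0
    refl[m] <- k
    a <- c(a + k * rev(a), k)
    f <- fm + k * bm
    b <- bm + k * fm
    E <- E * (1 - k * k)
  }
  list(ar = a, noise_power = E, reflection = refl)
}

#' Burg parametric power spectral density
#'
#' Evaluates the AR spectrum `E_m / |1 + sum_k a_k exp(-i 2 pi f k)|^2` on
#' `n_bins` equally spaced frequencies covering `[0, sample_rate/2)`
#' (`f` is the normalized frequency, frequency in Hz divided by the rate).
#'
#' @param ar_coeffs AR coefficients from [burg_fit].
#' @param noise_power Prediction-error power `E_m` from [burg_fit].
#' @param n_bins Number of frequency bins.
#' @param sample_rate Sampling rate in Hz.
#' @param psd_floor Clamp for the squared polynomial modulus; bins where the
#'   AR polynomial is (numerically) zero are floored, with a warning.
#' @return Numeric vector of length `n_bins`, strictly positive, with
#'   attributes `method = "burg"` and `freq_hz` (the bin frequencies).
#' @export
burg_psd <- function(ar_coeffs, noise_power, n_bins = 512L,
                     sample_rate = 44100, psd_floor = 1e-12) {
  n_bins <- as.integer(n_bins)
  f_norm <- (seq_len(n_bins) - 1) / n_bins / 2   # [0, 0.5)
  m <- length(ar_coeffs)
  A <- if (m == 0) {
    rep(1 + 0i, n_bins)
  } else {
    1 + exp(-2i * pi * outer(f_norm, seq_len(m))) %*% ar_coeffs
  }
  den <- Mod(A)^2
  if (any(den < psd_floor)) {
    warning("AR polynomial nearly zero at ", sum(den < psd_floor),
            " bin(s); clamping PSD denominator to the configured floor")
    den <- pmax(den, psd_floor)
  }
  psd <- as.numeric(noise_power / den)
  structure(psd, method = "burg", freq_hz = f_norm * sample_rate)
}

#' Biased autocorrelation matrix
#'
#' Builds the `M x M` Toeplitz autocorrelation matrix from the biased sample
#' autocovariances `r(0..M-1)` of the mean-removed signal.  The biased
#' (divide-by-n) estimator guarantees positive semi-definiteness.
#'
#' @param samples Numeric signal vector, `length >> size`.
#' @param size Matrix dimension `M`.
#' @return A symmetric `M x M` matrix.
#' @export
autocorrelation_matrix <- function(samples, size) {
  x <- as.numeric(samples)
  n <- length(x)
  size <- as.integer(size)
  if (size < 1) stop_arg("size must be >= 1")
  if (size > n) stop_arg("size must not exceed the signal length")
  x <- x - mean(x)
  # biased autocovariance via FFT (linear correlation through zero padding)
  nfft <- stats::nextn(2L * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE)) / nfft / n
  r <- ac[seq_len(size)]
  toeplitz(r)
}

#' MUSIC pseudospectrum
#'
#' Schmidt's eigenspace method: the autocorrelation matrix of the segment is
#' eigendecomposed, the `M - p` eigenvectors of smallest eigenvalue span the
#' noise subspace, and the pseudospectrum at frequency `f` is
#' `1 / sum_k |e(f)^H v_k|^2` with steering vector
#' `e(f) = [1, exp(-i 2 pi f), ..., exp(-i 2 pi f (M-1))]`.  Sinusoidal
#' components are (near-)orthogonal to the noise subspace, so the
#' pseudospectrum shows sharp peaks at their frequencies.
#'
#' @param samples Numeric signal vector.
#' @param config A [spectral_config] (uses `music_matrix_size`,
#'   `music_signal_dim`, `n_freq_bins`).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of length `n_freq_bins` with attributes
#'   `method = "music"` and `freq_hz`.
#' @export
music_pseudospectrum <- function(samples, config = spectral_config(),
                                 sample_rate = 44100) {
  M <- config$music_matrix_size
  p <- config$music_signal_dim
  if (p >= M) stop_arg("signal-subspace dimension must be < matrix size")
  R <- autocorrelation_matrix(samples, M)
  ev <- eigen(R, symmetric = TRUE)            # eigenvalues in decreasing order
  noise <- ev$vectors[, (p + 1L):M, drop = FALSE]
  n_bins <- config$n_freq_bins
  f_norm <- (seq_len(n_bins) - 1) / n_bins / 2
  E <- exp(-2i * pi * outer(f_norm, 0:(M - 1)))   # n_bins x M steering matrix
  proj <- E %*% noise
  ps <- 1 / rowSums(Mod(proj)^2)
  structure(as.numeric(ps), method = "music", freq_hz = f_norm * sample_rate)
}

#' Spectral feature vector for one segment
#'
#' Runs the configured estimator on a mean-removed segment and optionally
#' converts to decibels (`10*log10`), the representation fed to the
#' autoencoder.
#'
#' @param segment A [bee_audio] object.
#' @param method `"burg"` or `"music"`.
#' @param config A [spectral_config].
#' @return Numeric vector of length `config$n_freq_bins`.
#' @export
spectral_features <- function(segment, method = c("burg", "music"),
                              config = spectral_config()) {
  stopifnot(inherits(segment, "bee_audio"))
  method <- match.arg(method)
  v <- if (method == "burg") {
    fit <- burg_fit(segment$samples, config$ar_order)
    burg_psd(fit$ar, fit$noise_power, config$n_freq_bins,
             segment$sample_rate, config$psd_floor)
  } else {
    music_pseudospectrum(segment$samples, config, segment$sample_rate)
  }
  if (config$to_db) {
    out <- 10 * log10(pmax(as.numeric(v), 1e-300))
    attributes(out) <- attributes(v)
    out
  } else {
    v
  }
}
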