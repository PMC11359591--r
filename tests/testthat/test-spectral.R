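test_that("Burg fit recovers AR(1) dynamics and agrees with the reference estimator", {
  x <- withr::with_seed(101, as.numeric(arima.sim(list(ar = 0.9), 10000)))
  fit <- burg_fit(x, 1)
  # oracle 1: the true generator coefficient (prediction-polynomial sign)
  expect_lt(abs(fit$ar[1] + 0.9), 0.02)
  # oracle 2: empirical lag-1 autocorrelation (Yule-Walker estimate)
  r1 <- acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(fit$ar[1] + r1), 0.01)
  # cross-check against stats::ar.burg (independent implementation)
  ref <- ar(x, aic = FALSE, order.max = 1, method = "burg")
  expect_equal(fit$ar[1], -ref$ar[1], tolerance = 1e-8)
})

test_that("Burg on white noise gives small coefficients and E close to the variance", {
  x <- withr::with_seed(7, rnorm(20000))
  fit <- burg_fit(x, 4)
  expect_true(all(abs(fit$ar) < 0.05))
  expect_lt(abs(fit$noise_power - var(x)) / var(x), 0.05)
})

test_that("Burg reflection coefficients are bounded and the fit is stationary", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000)))
    fit <- burg_fit(x, 12)
    expect_true(all(abs(fit$reflection) <= 1))
    roots <- polyroot(c(1, fit$ar))
    expect_true(all(Mod(roots) > 1))  # roots of A(z^-1) outside unit circle
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(burg_fit(rep(3.2, 100), 4), "degenerate")
  expect_error(burg_fit(rnorm(10), 10), "order")
})

test_that("Burg PSD evaluates the AR spectrum formula exactly", {
  # hand-set coefficients: direct symbolic evaluation as oracle
  a <- c(-0.5, 0.2, 0.1)
  Em <- 2.5
  n_bins <- 64L
  psd <- burg_psd(a, Em, n_bins, sample_rate = 1)
  f <- (0:(n_bins - 1)) / n_bins / 2
  expected <- vapply(f, function(ff) {
    Em / Mod(1 + sum(a * exp(-2i * pi * ff * seq_along(a))))^2
  }, numeric(1))
  expect_equal(as.numeric(psd), expected, tolerance = 1e-10)

  # order 0: flat white-noise spectrum
  flat <- burg_psd(numeric(0), 1.7, 16)
  expect_equal(as.numeric(flat), rep(1.7, 16))

  # AR(1) a = -0.9: value at f = 0 is Em / (1 - 0.9)^2
  p0 <- burg_psd(-0.9, 1, 8)
  expect_equal(p0[1], 100)
})

test_that("AR(2) pole placement puts the PSD peak at the pole frequency", {
  # radius must be very close to 1: the spectral peak of an AR(2) sits at
  # cos(theta_peak) = (1 + r^2)/(2r) cos(theta), which drifts off the pole
  # angle quickly at low normalized frequencies
  fs <- 44100
  f0 <- 260
  r <- 0.998
  theta <- 2 * pi * f0 / fs
  a <- c(-2 * r * cos(theta), r^2)            # poles at r * exp(+-i theta)
  psd <- burg_psd(a, 1, 512, fs)
  peak_hz <- attr(psd, "freq_hz")[which.max(psd)]
  expect_lt(abs(peak_hz - f0), fs / 2 / 512)  # within one bin width
})

test_that("integrated Burg PSD approximates the process variance", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 20000)))
    fit <- burg_fit(x, 8)
    psd <- burg_psd(fit$ar, fit$noise_power, 1024, 1)
    # two-sided symmetry: mean over the one-sided grid integrates the spectrum
    expect_lt(abs(mean(psd) - var(x)) / var(x), 0.1)
  }
})

test_that("autocorrelation matrix is Toeplitz-symmetric with the expected entries", {
  x <- withr::with_seed(11, rnorm(50000, sd = 2))
  R <- autocorrelation_matrix(x, 8)
  expect_identical(R, t(R))
  expect_true(all(abs(diag(R) - 4) < 3 * 4 / sqrt(50000) * 3))
  expect_true(all(abs(R[upper.tri(R)]) < 3 * 4 / sqrt(50000) * 3))

  # pure cosine of amplitude A: r(0) = A^2 / 2
  fs <- 8000
  A <- 0.7
  x <- A * cos(2 * pi * 400 * (0:(fs - 1)) / fs)
  R <- autocorrelation_matrix(x, 4)
  expect_equal(R[1, 1], A^2 / 2, tolerance = 1e-6)

  ev <- eigen(autocorrelation_matrix(rnorm(1000), 16), symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > -1e-10))        # biased estimator is PSD
})

test_that("MUSIC locates one and two sinusoids within one bin at SNR 10 dB", {
  fs <- 44100
  n <- fs
  t <- (0:(n - 1)) / fs
  bin_w <- fs / 2 / 512

  s1 <- sin(2 * pi * 500 * t)
  x1 <- s1 + withr::with_seed(21, rnorm(n, sd = sqrt(mean(s1^2) / 10)))
  ps <- music_pseudospectrum(x1, spectral_config(music_matrix_size = 64L,
                                                 music_signal_dim = 2L), fs)
  expect_lt(abs(attr(ps, "freq_hz")[which.max(ps)] - 500), bin_w + 1e-9)

  s2 <- sin(2 * pi * 400 * t) + sin(2 * pi * 460 * t)
  x2 <- s2 + withr::with_seed(22, rnorm(n, sd = sqrt(mean(s2^2) / 10)))
  ps2 <- music_pseudospectrum(x2, spectral_config(music_matrix_size = 64L,
                                                  music_signal_dim = 4L), fs)
  v <- as.numeric(ps2)
  local_max <- which(diff(sign(diff(v))) == -2) + 1L
  peaks_hz <- attr(ps2, "freq_hz")[local_max[order(v[local_max], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(peaks_hz - 400)), bin_w + 1e-9)
  expect_lt(min(abs(peaks_hz - 460)), bin_w + 1e-9)
})

test_that("MUSIC pseudospectrum is invariant to amplitude scaling", {
  x <- generate_buzz(buzz_params(seed = 5))$samples
  cfg <- spectral_config()
  a <- music_pseudospectrum(x, cfg)
  b <- music_pseudospectrum(5 * x, cfg)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-8)
})

test_that("noiseless sinusoids give diverging pseudospectrum peaks", {
  fs <- 44100
  t <- (0:(fs / 2 - 1)) / fs
  x <- sin(2 * pi * 700 * t) + 0.5 * sin(2 * pi * 1900 * t)
  ps <- music_pseudospectrum(x, spectral_config(music_matrix_size = 64L,
                                                music_signal_dim = 4L), fs)
  expect_gt(max(ps) / median(ps), 100)
})

test_that("white noise with an empty signal subspace is flat", {
  x <- withr::with_seed(31, rnorm(44100))
  ps <- music_pseudospectrum(x, spectral_config(music_matrix_size = 32L,
                                                music_signal_dim = 0L), 44100)
  expect_lt(max(ps) / min(ps), 2)
})

test_that("spectral feature vectors have the configured dimension and are finite", {
  seg <- generate_buzz(buzz_params(seed = 9))
  for (m in c("burg", "music")) {
    v <- spectral_features(seg, m, spectral_config(n_freq_bins = 256L))
    expect_length(as.numeric(v), 256L)
    expect_true(all(is.finite(v)))
    expect_identical(attr(v, "method"), m)
  }
  # raw (non-dB) spectral values are strictly positive
  v <- spectral_features(seg, "burg", spectral_config(to_db = FALSE))
  expect_true(all(v > 0))
})
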