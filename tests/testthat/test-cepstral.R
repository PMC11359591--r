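test_that("mel conversion matches the formula and inverts cleanly", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 1127 * log(2))
  for (x in c(100, 1000, 3000)) {
    expect_equal(hz_to_mel(mel_to_hz(x)), x, tolerance = 1e-9)
  }
  expect_error(hz_to_mel(-1), "nonnegative")
  # monotone increasing
  f <- seq(0, 20000, by = 100)
  expect_true(all(diff(hz_to_mel(f)) > 0))
})

test_that("mel filterbank centers are equally spaced on the mel scale", {
  cfg <- cepstral_config(n_filters = 3L, fmin = 0, fmax = 22050,
                         frame_len = 2048L)
  fb <- mel_filterbank(cfg, 44100)
  centers <- attr(fb, "center_hz")
  expect_equal(hz_to_mel(centers), hz_to_mel(22050) * (1:3) / 4, tolerance = 1e-9)
  expect_true(all(rowSums(fb) > 0))
  expect_true(all(fb >= 0))
  # center bins non-decreasing across filters
  peak_bins <- apply(fb, 1, which.max)
  expect_true(all(diff(peak_bins) >= 0))
})

test_that("default 120-filter bank leaves no filter without support", {
  fb <- mel_filterbank(cepstral_config(), 44100)
  expect_equal(dim(fb), c(120L, 1025L))
  expect_true(all(rowSums(fb) > 0))
  expect_error(mel_filterbank(cepstral_config(n_filters = 120L, n_fft = 256L,
                                              frame_len = 256L, hop = 128L), 44100),
               "no nonzero bin")
})

test_that("cepstral DCT matches a brute-force double loop", {
  for (seed in 1:3) {
    y <- withr::with_seed(seed, runif(17, 0.1, 5))
    logy <- log10(y)
    M <- length(y)
    brute <- numeric(M)
    for (i in 1:M) {
      acc <- 0
      for (m in 1:M) {
        acc <- acc + logy[m] * cos((2 * m - 1) * i * pi / (2 * M))
      }
      brute[i] <- sqrt(2 / M) * acc
    }
    expect_equal(cepstral_dct(logy), brute, tolerance = 1e-10)
  }
})

test_that("gammatone response has unit center gain and -3 dB at one bandwidth (N=1)", {
  expect_equal(gammatone_response(1000, 1000, 100, 1), 1 + 0i)
  expect_equal(Mod(gammatone_response(1000, 1000, 130, 4)), 1)
  expect_equal(Mod(gammatone_response(1100, 1000, 100, 1)), 1 / sqrt(2))
  expect_equal(20 * log10(Mod(gammatone_response(1100, 1000, 100, 1))), -3.01,
               tolerance = 0.01)
  # even magnitude symmetry about the center
  for (d in c(10, 55, 300)) {
    expect_equal(Mod(gammatone_response(1000 + d, 1000, 80, 4)),
                 Mod(gammatone_response(1000 - d, 1000, 80, 4)))
  }
})

test_that("gammatone filterbank peaks at the bin nearest each center frequency", {
  cfg <- cepstral_config()               # 2048-point FFT: 21.5 Hz bins
  fb <- gammatone_filterbank(cfg, 44100)
  bin_hz <- (0:(cfg$n_fft %/% 2)) * 44100 / cfg$n_fft
  centers <- attr(fb, "center_hz")
  for (f0 in c(300, 1000, 3000, 6000)) {
    m <- which.min(abs(centers - f0))
    expect_equal(which.max(fb[m, ]), which.min(abs(bin_hz - centers[m])))
  }
  # where the bandwidth dwarfs the bin spacing the peak value is ~ 1
  wide <- which(24.7 * (4.37 * centers / 1000 + 1) > 100)
  expect_true(all(apply(fb[wide, ], 1, max) > 0.9))
})

test_that("a pure 1 kHz tone concentrates energy in the nearest gammatone filter", {
  seg <- make_tone(1000, duration_s = 0.1)
  cfg <- tiny_cepstral()
  fb <- gammatone_filterbank(cfg, 44100)
  P <- beebuzz:::frame_power_spectra(seg$samples, cfg)
  Y <- rowMeans(fb %*% P)
  expect_equal(which.max(Y),
               which.min(abs(attr(fb, "center_hz") - 1000)))
})

test_that("identical frames make aggregation a no-op", {
  cfg <- cepstral_config(frame_len = 1024L, hop = 1024L, n_filters = 24L,
                         fmin = 50, fmax = 8000)
  frame <- withr::with_seed(4, runif(1024, -0.5, 0.5))
  seg <- bee_audio(rep(frame, 4), 44100)
  v <- mfcc(seg, cfg)
  one <- mfcc(bee_audio(frame, 44100), cfg)
  expect_equal(as.numeric(v), as.numeric(one), tolerance = 1e-12)
})

test_that("mfcc matches a naive re-evaluation of the pipeline, including gain shifts", {
  cfg <- cepstral_config(frame_len = 512L, hop = 512L, n_filters = 12L,
                         fmin = 100, fmax = 8000)
  x <- withr::with_seed(8, runif(512, -0.8, 0.8))
  seg <- bee_audio(x, 44100)

  # naive oracle: window, FFT, |X|^2, filterbank, log10, double-loop DCT
  w <- 0.54 - 0.46 * cos(2 * pi * (0:511) / 511)
  X <- fft(x * w)
  pow <- Mod(X[1:257])^2
  fb <- mel_filterbank(cfg, 44100)
  Y <- pmax(as.numeric(fb %*% pow), 1e-12)
  M <- 12
  oracle <- vapply(1:M, function(i) {
    sqrt(2 / M) * sum(log10(Y) * cos((2 * (1:M) - 1) * i * pi / (2 * M)))
  }, numeric(1))
  expect_equal(as.numeric(mfcc(seg, cfg)), oracle, tolerance = 1e-10)

  # gain g scales energies by g^2, shifting each log10 Y by 2 log10 g
  shift <- vapply(1:M, function(i) {
    sqrt(2 / M) * sum((log10(Y) + 2 * log10(0.5)) * cos((2 * (1:M) - 1) * i * pi / (2 * M)))
  }, numeric(1))
  v_half <- as.numeric(mfcc(bee_audio(x * 0.5, 44100), cfg))
  expect_equal(v_half, shift, tolerance = 1e-9)
})

test_that("white-noise MFCC puts most magnitude in the first coefficient", {
  cfg <- cepstral_config(frame_len = 256L, hop = 256L, n_filters = 20L,
                         fmin = 50, fmax = 8000)
  c1 <- numeric(50); chigh <- numeric(50)
  for (r in 1:50) {
    x <- withr::with_seed(1000 + r, runif(256, -0.9, 0.9))
    v <- as.numeric(mfcc(bee_audio(x, 44100), cfg))
    c1[r] <- abs(v[1])
    chigh[r] <- mean(abs(v[10:19]))
  }
  expect_gt(mean(c1), mean(chigh))
})

test_that("cepstral extraction is deterministic and respects the shared contract", {
  seg <- generate_buzz(buzz_params(seed = 12, duration_s = 0.2))
  cfg <- tiny_cepstral()
  expect_identical(mfcc(seg, cfg), mfcc(seg, cfg))
  m <- mfcc(seg, cfg); g <- gtcc(seg, cfg)
  expect_length(as.numeric(m), cfg$n_coeffs)
  expect_length(as.numeric(g), cfg$n_coeffs)
  expect_identical(attr(m, "method"), "mfcc")
  expect_identical(attr(g, "method"), "gtcc")
  # default dimension contract: 120 coefficients per segment
  full <- mfcc(generate_buzz(buzz_params(seed = 13)))
  expect_length(as.numeric(full), 120L)
})

test_that("filterbank energies are nonnegative and silence is floored with a warning", {
  cfg <- tiny_cepstral()
  fb <- mel_filterbank(cfg, 44100)
  x <- withr::with_seed(3, rnorm(2048))
  P <- beebuzz:::frame_power_spectra(x, cfg)
  expect_true(all(fb %*% P >= 0))
  expect_warning(mfcc(bee_audio(numeric(1024), 44100), cfg), "silent")
})
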