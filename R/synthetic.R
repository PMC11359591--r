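#' Parameters of the synthetic buzz generator
#'
#' Describes a bee-like flight sound: a harmonic series on a wingbeat
#' fundamental with slow frequency jitter, sinusoidal amplitude modulation
#' and additive white Gaussian noise.  Worker defaults follow the ~260 Hz
#' wingbeat rate of foraging workers; the drone fundamental defaults to
#' 200 Hz — a fixture choice motivated by drones' larger bodies and longer
#' wings (lower wingbeat rate), not a field measurement.
#'
#' @param fundamental_hz Wingbeat fundamental in Hz.
#' @param n_harmonics Number of harmonics (including the fundamental).
#' @param harmonic_decay Amplitude ratio between consecutive harmonics.
#' @param freq_jitter_cents Peak slow frequency jitter, in cents.
#' @param am_depth Amplitude-modulation depth in `[0, 1]`.
#' @param am_rate_hz Amplitude-modulation rate in Hz.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` disables noise).
#' @param duration_s Clip duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Generator seed.
#' @return A list of class `buzz_params`.
#' @export
buzz_params <- function(fundamental_hz = 260, n_harmonics = 8,
                        harmonic_decay = 0.7, freq_jitter_cents = 30,
                        am_depth = 0.3, am_rate_hz = 8, snr_db = 20,
                        duration_s = 1, sample_rate = 44100, seed = 1L) {
  if (am_depth < 0 || am_depth > 1) stop_arg("am_depth must be in [0, 1]")
  if (!is.finite(fundamental_hz) || fundamental_hz <= 0) {
    stop_arg("fundamental_hz must be positive")
  }
  if (fundamental_hz * n_harmonics >= sample_rate / 2) {
    stop_arg("highest harmonic exceeds the Nyquist frequency (aliasing)")
  }
  structure(list(fundamental_hz = fundamental_hz,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 freq_jitter_cents = freq_jitter_cents,
                 am_depth = am_depth, am_rate_hz = am_rate_hz,
                 snr_db = snr_db, duration_s = duration_s,
                 sample_rate = as.integer(sample_rate), seed = as.integer(seed)),
            class = "buzz_params")
}

#' Generate one synthetic buzz clip
#'
#' Sums `n_harmonics` sinusoids at multiples of the (jittered) fundamental
#' with geometrically decaying amplitudes, applies sinusoidal amplitude
#' modulation, adds white Gaussian noise at the requested SNR, and
#' peak-normalizes to 0.9.  Deterministic given the seed.
#'
#' @param params A [buzz_params] object.
#' @param label Class label to attach.
#' @param source_id Provenance string.
#' @return A [bee_audio] segment of `round(duration_s * sample_rate)`
#'   samples.
#' @export
generate_buzz <- function(params, label = "unknown", source_id = "synthetic") {
  stopifnot(inherits(params, "buzz_params"))
  fs <- params$sample_rate
  n <- round(params$duration_s * fs)
  t <- (0:(n - 1)) / fs
  with_local_seed(params$seed, {
    # slow jitter: random control points at ~8 Hz, linearly interpolated,
    # applied as a multiplicative pitch factor bounded by the cents limit
    if (params$freq_jitter_cents > 0) {
      n_ctrl <- max(3L, ceiling(params$duration_s * 8) + 2L)
      ctrl <- runif(n_ctrl, -1, 1) * params$freq_jitter_cents
      jit <- approx(seq(0, params$duration_s, length.out = n_ctrl), ctrl,
                    xout = t, rule = 2)$y
      factor <- 2^(jit / 1200)
    } else {
      factor <- rep(1, n)
    }
    phase <- 2 * pi * params$fundamental_hz * cumsum(factor) / fs
    amps <- params$harmonic_decay^(seq_len(params$n_harmonics) - 1)
    sig <- numeric(n)
    for (k in seq_len(params$n_harmonics)) {
      sig <- sig + amps[k] * sin(k * phase)
    }
    if (params$am_depth > 0) {
      am_phase <- runif(1, 0, 2 * pi)
      sig <- sig * (1 + params$am_depth * sin(2 * pi * params$am_rate_hz * t + am_phase))
    }
    if (is.finite(params$snr_db)) {
      noise_sd <- sqrt(mean(sig^2) / 10^(params$snr_db / 10))
      sig <- sig + rnorm(n, sd = noise_sd)
    }
    sig <- 0.9 * sig / max(abs(sig))
    bee_audio(sig, fs, label = label, source_id = source_id)
  })
}

#' Generate a labelled synthetic corpus
#'
#' Draws `n_worker` worker clips and `n_drone` drone clips with per-clip
#' seeds derived from the master seed, so the corpus is reproducible and
#' every clip differs in its jitter/noise realization.
#'
#' @param n_worker,n_drone Clip counts.
#' @param worker_params,drone_params [buzz_params] for each class (their
#'   `seed` field is overridden per clip).
#' @param seed Master seed.
#' @return A list of labelled [bee_audio] segments, workers first.
#' @export
generate_dataset <- function(n_worker, n_drone,
                             worker_params = buzz_params(fundamental_hz = 260),
                             drone_params = buzz_params(fundamental_hz = 200),
                             seed = 1L) {
  if (n_worker < 0 || n_drone < 0) stop_arg("counts must be nonnegative")
  seeds <- derive_seeds(seed, n_worker + n_drone)
  make <- function(i, params, label) {
    p <- params
    p$seed <- as.integer(seeds[i])
    generate_buzz(p, label = label,
                  source_id = sprintf("%s_%04d", label,
                                      if (label == "worker") i else i - n_worker))
  }
  c(
    lapply(seq_len(n_worker), make, params = worker_params, label = "worker"),
    lapply(seq_len(n_drone) + n_worker, make, params = drone_params, label = "drone")
  )
}

#' Write a synthetic corpus as WAV files
#'
#' Writes clips into `dir/worker/` and `dir/drone/`, the layout consumed by
#' [load_audio_dir].
#'
#' @param segments Labelled [bee_audio] list (e.g. from [generate_dataset]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(segments, dir) {
  for (cls in unique(vapply(segments, function(s) s$label, character(1)))) {
    dir.create(file.path(dir, cls), recursive = TRUE, showWarnings = FALSE)
  }
  for (s in segments) {
    write_wav(s, file.path(dir, s$label, paste0(s$source_id, ".wav")))
  }
  invisible(dir)
}

#' Generate synthetic reconstruction-error samples
#'
#' Seeded Gaussian draws from two class models (negative draws truncated at
#' zero), for exercising the thresholding stage without audio or training.
#'
#' @param model1,model2 `gaussian_class_model`s for the worker and drone
#'   class respectively (see [fit_gaussian]).
#' @param n1,n2 Sample counts per class.
#' @param seed Seed.
#' @return An error data frame with columns `mse`, `label`, `source_id`.
#' @export
generate_error_samples <- function(model1, model2, n1, n2, seed = 1L) {
  stopifnot(inherits(model1, "gaussian_class_model"),
            inherits(model2, "gaussian_class_model"))
  with_local_seed(seed, {
    mse <- c(rnorm(n1, model1$mu, model1$sigma),
             rnorm(n2, model2$mu, model2$sigma))
    data.frame(
      mse = pmax(0, mse),
      label = rep(c("worker", "drone"), c(n1, n2)),
      source_id = c(sprintf("sim_worker_%05d", seq_len(n1)),
                    sprintf("sim_drone_%05d", seq_len(n2))),
      stringsAsFactors = FALSE
    )
  })
}
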