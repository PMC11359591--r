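#' Autoencoder configuration
#'
#' Architecture and optimization settings for the one-class autoencoder.
#' The encoder narrows from `input_dim` down to an 8-neuron code through
#' `n_encoder_hidden` hidden layers; the decoder has one hidden layer fewer
#' than the encoder.  Hidden layers use ReLU, the output layer a sigmoid,
#' so inputs are min-max normalized to `[0, 1]` before training.
#'
#' @param input_dim Feature dimension (512 for spectral, 120 for cepstral
#'   features).
#' @param n_encoder_hidden Number of encoder hidden layers, 1 to 4.
#' @param code_dim Bottleneck width (default 8).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed for weight initialization and batch shuffling.
#' @param validation_fraction Fraction of the training features held out to
#'   report generalization error; decision thresholds are computed from the
#'   training split only.
#' @return A list of class `autoencoder_config`.
#' @export
autoencoder_config <- function(input_dim, n_encoder_hidden = 2L, code_dim = 8L,
                               epochs = 100L, batch_size = 32L,
                               learning_rate = 1e-3, seed = 1L,
                               validation_fraction = 0.1) {
  if (!n_encoder_hidden %in% 1:4) stop_arg("n_encoder_hidden must be 1, 2, 3 or 4")
  if (code_dim >= input_dim) stop_arg("code_dim must be smaller than input_dim")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop_arg("validation_fraction must be in [0, 1)")
  }
  structure(list(input_dim = as.integer(input_dim),
                 n_encoder_hidden = as.integer(n_encoder_hidden),
                 code_dim = as.integer(code_dim), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "autoencoder_config")
}

#' Layer sizes of the bottleneck architecture
#'
#' Encoder sizes interpolate geometrically from `input_dim` down to
#' `code_dim` (rounded to integers): with `h` hidden layers the size of
#' layer `i` is `input_dim^(1 - t) * code_dim^t` at `t = i/(h + 1)`.  The
#' decoder mirrors the encoder with its last hidden layer dropped, ending in
#' an `input_dim` output, so it has `h - 1` hidden layers.
#'
#' @param input_dim,n_encoder_hidden,code_dim As in [autoencoder_config].
#' @return A list with `encoder` (input through code), `decoder_hidden`, and
#'   `full` (every layer size from input to output).
#' @export
autoencoder_layer_sizes <- function(input_dim, n_encoder_hidden, code_dim = 8L) {
  h <- as.integer(n_encoder_hidden)
  t <- (0:(h + 1L)) / (h + 1L)
  enc <- round(input_dim^(1 - t) * code_dim^t)
  if (any(diff(enc) >= 0)) {
    stop_arg("geometric interpolation produced non-decreasing layer sizes; ",
             "choose a smaller n_encoder_hidden or wider input")
  }
  enc_hidden <- enc[seq(2L, h + 1L)]
  dec_hidden <- rev(enc_hidden)[seq_len(max(0L, h - 1L))]
  list(encoder = as.integer(enc), decoder_hidden = as.integer(dec_hidden),
       full = as.integer(c(enc, dec_hidden, input_dim)))
}

#' Build an untrained autoencoder
#'
#' Allocates the layer structure of [autoencoder_layer_sizes] and draws
#' initial weights from the Glorot uniform distribution using the seeded
#' generator; identical seed and config give identical initial weights.
#'
#' @param config An [autoencoder_config].
#' @return An object of class `bee_autoencoder` (untrained: no normalizer).
#' @export
build_autoencoder <- function(config) {
  stopifnot(inherits(config, "autoencoder_config"))
  sizes <- autoencoder_layer_sizes(config$input_dim, config$n_encoder_hidden,
                                   config$code_dim)$full
  n_layers <- length(sizes) - 1L
  weights <- with_local_seed(config$seed, {
    lapply(seq_len(n_layers), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1]
      s <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out),
           b = numeric(fan_out))
    })
  })
  structure(list(layer_sizes = sizes, weights = weights, config = config,
                 normalizer = NULL, loss_history = NULL),
            class = "bee_autoencoder")
}

#' @export
print.bee_autoencoder <- function(x, ...) {
  cat(sprintf("<bee_autoencoder> layers [%s]%s\n",
              paste(x$layer_sizes, collapse = " "),
              if (is.null(x$normalizer)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Fit a per-dimension min-max normalizer
#'
#' The sigmoid output layer constrains reconstruction targets to `(0, 1)`,
#' so features are mapped to `[0, 1]` by per-dimension min-max learned on
#' the training data.  Constant dimensions map to 0.5; test values outside
#' the training range are clipped.
#'
#' @param values Numeric matrix, one row per training feature vector.
#' @return A list of class `feature_normalizer` with `min` and `max`.
#' @export
fit_normalizer <- function(values) {
  if (inherits(values, "bee_features")) values <- values$values
  values <- as.matrix(values)
  if (nrow(values) == 0) stop_arg("cannot fit a normalizer on an empty set")
  structure(list(min = apply(values, 2, min), max = apply(values, 2, max)),
            class = "feature_normalizer")
}

#' Apply a fitted normalizer
#' @param normalizer A `feature_normalizer` from [fit_normalizer].
#' @param values Numeric matrix (or vector) of raw features.
#' @return Matrix of values in `[0, 1]`.
#' @export
apply_normalizer <- function(normalizer, values) {
  if (inherits(values, "bee_features")) values <- values$values
  values <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  rng <- normalizer$max - normalizer$min
  out <- sweep(sweep(values, 2, normalizer$min), 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0.5
  out[out < 0] <- 0   # clip test values outside the training range
  out[out > 1] <- 1
  out
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass on a normalized matrix X (n x input_dim); returns activations
# per layer (A[[1]] = X) and pre-activations Z for backprop.
ae_forward <- function(model, X, keep = FALSE) {
  L <- length(model$weights)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$weights[[l]]$W, 2, model$weights[[l]]$b, "+")
    A[[l + 1]] <- if (l < L) relu(Z[[l]]) else sigmoid(Z[[l]])
  }
  if (keep) list(A = A, Z = Z) else A[[L + 1]]
}

#' Train the autoencoder on worker-bee features
#'
#' One-class training: the network learns to reconstruct worker-bee feature
#' vectors by minimizing mean-squared reconstruction error with mini-batch
#' Adam.  A validation fraction is held out (seeded split) purely to report
#' generalization MSE; thresholds later use the training split.  Training is
#' fully reproducible given the config seed.
#'
#' @param model A `bee_autoencoder` from [build_autoencoder].
#' @param features A `bee_features` object or numeric matrix whose rows are
#'   worker-class feature vectors of dimension `input_dim`.
#' @return The trained model, with `normalizer`, `loss_history` (per-epoch
#'   training MSE), `val_mse`, and the `train_idx`/`val_idx` of the split.
#' @export
train_autoencoder <- function(model, features) {
  stopifnot(inherits(model, "bee_autoencoder"))
  values <- if (inherits(features, "bee_features")) features$values else as.matrix(features)
  cfg <- model$config
  if (ncol(values) != cfg$input_dim) {
    stop_arg("feature dimension ", ncol(values), " does not match input_dim ",
             cfg$input_dim)
  }
  n <- nrow(values)
  if (n < 2) stop_arg("need at least 2 training vectors")

  with_local_seed(cfg$seed + 1L, {
    n_val <- floor(cfg$validation_fraction * n)
    val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    normalizer <- fit_normalizer(values[train_idx, , drop = FALSE])
    Xtr <- apply_normalizer(normalizer, values[train_idx, , drop = FALSE])
    ntr <- nrow(Xtr)

    L <- length(model$weights)
    adam_m <- lapply(model$weights, function(w) list(W = w$W * 0, b = w$b * 0))
    adam_v <- adam_m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    loss_history <- numeric(cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(ntr)
      batch_starts <- seq(1L, ntr, by = cfg$batch_size)
      epoch_loss <- 0
      for (bs in batch_starts) {
        idx <- perm[bs:min(bs + cfg$batch_size - 1L, ntr)]
        X <- Xtr[idx, , drop = FALSE]
        fw <- ae_forward(model, X, keep = TRUE)
        Y <- fw$A[[L + 1]]
        diffm <- Y - X
        nb <- nrow(X)
        loss <- mean(diffm^2)
        if (!is.finite(loss)) {
          stop_arg("training diverged (non-finite loss) at epoch ", epoch)
        }
        epoch_loss <- epoch_loss + loss * nb

        # backprop: dL/dZ_L with sigmoid output, MSE averaged over n*d
        delta <- (2 * diffm / (nb * ncol(X))) * Y * (1 - Y)
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(model$weights[[l]]$W)) * (fw$Z[[l - 1]] > 0)
          }
          step_l <- if (l == L) { step <- step + 1L; step } else step
          adam_m[[l]]$W <- beta1 * adam_m[[l]]$W + (1 - beta1) * gW
          adam_m[[l]]$b <- beta1 * adam_m[[l]]$b + (1 - beta1) * gb
          adam_v[[l]]$W <- beta2 * adam_v[[l]]$W + (1 - beta2) * gW^2
          adam_v[[l]]$b <- beta2 * adam_v[[l]]$b + (1 - beta2) * gb^2
          mh <- 1 - beta1^step_l; vh <- 1 - beta2^step_l
          model$weights[[l]]$W <- model$weights[[l]]$W -
            cfg$learning_rate * (adam_m[[l]]$W / mh) / (sqrt(adam_v[[l]]$W / vh) + eps)
          model$weights[[l]]$b <- model$weights[[l]]$b -
            cfg$learning_rate * (adam_m[[l]]$b / mh) / (sqrt(adam_v[[l]]$b / vh) + eps)
        }
      }
      loss_history[epoch] <- epoch_loss / ntr
    }

    model$normalizer <- normalizer
    model$loss_history <- loss_history
    model$train_idx <- train_idx
    model$val_idx <- val_idx
    model$val_mse <- if (length(val_idx) > 0) {
      Xv <- apply_normalizer(normalizer, values[val_idx, , drop = FALSE])
      mean(rowMeans((ae_forward(model, Xv) - Xv)^2))
    } else {
      NA_real_
    }
    model
  })
}

#' Per-segment reconstruction error
#'
#' Normalizes the features with the model's stored normalizer, runs them
#' through the network, and returns the mean squared reconstruction error
#' per segment — the one-dimensional statistic on which classification
#' operates.
#'
#' @param model A trained `bee_autoencoder`.
#' @param features A `bee_features` object or numeric matrix/vector.
#' @return A data frame of error samples with columns `mse`, `label`,
#'   `source_id`.
#' @export
reconstruction_error <- function(model, features) {
  stopifnot(inherits(model, "bee_autoencoder"))
  if (is.null(model$normalizer)) stop_arg("model has not been trained")
  if (inherits(features, "bee_features")) {
    values <- features$values
    labels <- features$labels
    ids <- features$source_ids
  } else {
    values <- if (is.matrix(features)) features else matrix(features, nrow = 1)
    labels <- rep("unknown", nrow(values))
    ids <- rep("", nrow(values))
  }
  if (ncol(values) != model$config$input_dim) {
    stop_arg("feature dimension ", ncol(values), " does not match input_dim ",
             model$config$input_dim)
  }
  X <- apply_normalizer(model$normalizer, values)
  Y <- ae_forward(model, X)
  data.frame(mse = rowMeans((Y - X)^2), label = labels, source_id = ids,
             stringsAsFactors = FALSE)
}
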