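#' k-sigma decision threshold
#'
#' `T_k = mean(MSEtrain) + k * std(MSEtrain)` computed from worker-class
#' training reconstruction errors only; `std` is the sample standard
#' deviation (n-1 denominator).  `k = 1, 2, 3` give the thresholds T1, T2,
#' T3.
#'
#' @param train_errors Error data frame (from [reconstruction_error]) or
#'   numeric vector of worker-class training MSE values.
#' @param k Number of standard deviations.
#' @return The threshold value.
#' @export
ksigma_threshold <- function(train_errors, k = 1) {
  x <- error_values(train_errors, require_label = "worker")
  if (length(x) < 2) stop_arg("need at least 2 training errors")
  mean(x) + k * sd(x)
}

#' Gaussian model of a class's reconstruction errors
#'
#' Fits a normal density to a class's MSE samples (mean and n-1 standard
#' deviation).  The error histograms produced by the autoencoder are close
#' to normal, which is what makes the maximum-likelihood threshold of
#' [ml_threshold] a good empirical Bayes boundary.
#'
#' @param errors Error data frame or numeric vector of MSE values.
#' @param prior Prior class probability in `(0, 1)`.
#' @return A list of class `gaussian_class_model` with `mu`, `sigma`,
#'   `prior`.
#' @export
fit_gaussian <- function(errors, prior = 0.5) {
  x <- error_values(errors)
  if (length(x) < 2) stop_arg("need at least 2 samples to fit a Gaussian")
  s <- sd(x)
  if (s <= 0) stop_arg("degenerate fit: zero variance")
  if (prior <= 0 || prior >= 1) stop_arg("prior must be in (0, 1)")
  structure(list(mu = mean(x), sigma = s, prior = prior),
            class = "gaussian_class_model")
}

#' Maximum-likelihood (empirical Bayes) threshold
#'
#' Returns the reconstruction-error value `T*` where the prior-weighted
#' Gaussian densities of the two classes intersect:
#' `prior1 * N(x; mu1, sigma1^2) = prior2 * N(x; mu2, sigma2^2)`.
#' Classifying "class 2 iff error > T*" then assigns each error to the class
#' of higher posterior probability on the interval between the class means,
#' i.e. the empirical Bayes rule minimizing misclassification under the
#' fitted models.
#'
#' With unequal sigmas the intersection equation is quadratic; only the root
#' inside `(mu1, mu2)` realizes "higher error means anomaly", so that root
#' is returned.  With (numerically) equal sigmas the closed form
#' `(mu1 + mu2)/2 + sigma^2 log(prior1/prior2)/(mu2 - mu1)` is used.  If no
#' root falls between the means (pathological overlap), the function falls
#' back to the candidate root minimizing empirical misclassification on
#' `calibration_errors`, with a warning.
#'
#' @param class1 `gaussian_class_model` of the low-error (worker) class.
#' @param class2 `gaussian_class_model` of the high-error (drone) class;
#'   must have `mu2 > mu1`.
#' @param calibration_errors Optional labelled error data frame used only by
#'   the fallback.
#' @return The threshold `T*`.
#' @export
ml_threshold <- function(class1, class2, calibration_errors = NULL) {
  stopifnot(inherits(class1, "gaussian_class_model"),
            inherits(class2, "gaussian_class_model"))
  m1 <- class1$mu; s1 <- class1$sigma; p1 <- class1$prior
  m2 <- class2$mu; s2 <- class2$sigma; p2 <- class2$prior
  if (m1 >= m2) stop_arg("class1 must have the smaller mean error")

  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    return((m1 + m2) / 2 + s1^2 * log(p1 / p2) / (m2 - m1))
  }
  # log p1 - log s1 - (x-m1)^2/(2 s1^2) = log p2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((p1 * s2) / (p2 * s1))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    stop_arg("prior-weighted densities never intersect (negative discriminant)")
  }
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) >= 1) return(inside[1])

  warning("no density intersection between the class means; falling back to ",
          "the root minimizing empirical misclassification")
  if (is.null(calibration_errors)) {
    stop_arg("fallback requires labelled calibration_errors")
  }
  miscls <- vapply(roots, function(t) {
    pred <- ifelse(calibration_errors$mse > t, "drone", "worker")
    mean(pred != calibration_errors$label)
  }, numeric(1))
  roots[which.min(miscls)]
}

#' Classify reconstruction errors by a threshold
#'
#' Drone (anomaly) iff the error exceeds the threshold; ties go to worker.
#'
#' @param errors Error data frame or numeric vector of MSE values.
#' @param threshold Decision threshold.
#' @return Character vector of `"worker"`/`"drone"` predictions.
#' @export
classify_errors <- function(errors, threshold) {
  x <- error_values(errors)
  ifelse(x > threshold, "drone", "worker")
}

#' Compute the full threshold set
#'
#' T1-T3 from the worker-class training errors (k-sigma rule) and T* from
#' Gaussian fits to labelled calibration errors of both classes.  Unless
#' priors are supplied, they default to the empirical class proportions of
#' the calibration data.
#'
#' @param train_errors Worker-class training error data frame.
#' @param calibration_errors Labelled error data frame containing both
#'   classes (used only for T*).
#' @param priors Optional length-2 vector `c(worker, drone)` summing to 1.
#' @return A list of class `threshold_set` with `t1`, `t2`, `t3`, `t_star`,
#'   `worker_model`, `drone_model`.
#' @export
compute_thresholds <- function(train_errors, calibration_errors, priors = NULL) {
  t123 <- vapply(1:3, function(k) ksigma_threshold(train_errors, k), numeric(1))
  w <- calibration_errors[calibration_errors$label == "worker", , drop = FALSE]
  d <- calibration_errors[calibration_errors$label == "drone", , drop = FALSE]
  if (nrow(w) < 2 || nrow(d) < 2) {
    stop_arg("calibration data must contain at least 2 errors of each class")
  }
  if (is.null(priors)) {
    priors <- c(nrow(w), nrow(d)) / (nrow(w) + nrow(d))
  }
  if (abs(sum(priors) - 1) > 1e-9) stop_arg("priors must sum to 1")
  wm <- fit_gaussian(w$mse, prior = priors[1])
  dm <- fit_gaussian(d$mse, prior = priors[2])
  if (wm$mu >= dm$mu) {
    stop_arg("worker calibration errors are not smaller than drone errors ",
             "on average; the anomaly assumption is violated")
  }
  structure(list(t1 = t123[1], t2 = t123[2], t3 = t123[3],
                 t_star = ml_threshold(wm, dm, calibration_errors),
                 worker_model = wm, drone_model = dm),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> T1=%.4g T2=%.4g T3=%.4g T*=%.4g\n",
              x$t1, x$t2, x$t3, x$t_star))
  cat(sprintf("  worker ~ N(%.4g, %.4g^2) prior %.2f | drone ~ N(%.4g, %.4g^2) prior %.2f\n",
              x$worker_model$mu, x$worker_model$sigma, x$worker_model$prior,
              x$drone_model$mu, x$drone_model$sigma, x$drone_model$prior))
  invisible(x)
}

# Accept either a numeric vector or an error data frame; optionally insist
# every sample carries the given label (k-sigma thresholds must be computed
# from worker errors only).
error_values <- function(errors, require_label = NULL) {
  if (is.data.frame(errors)) {
    if (!is.null(require_label)) {
      errors <- errors[errors$label == require_label, , drop = FALSE]
    }
    x <- errors$mse
  } else {
    x <- as.numeric(errors)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_arg("reconstruction errors must be finite and nonnegative")
  }
  x
}
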