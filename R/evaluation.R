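#' Confusion counts with worker as the positive class
#'
#' Tallies true/false positives/negatives following the convention used
#' throughout this package: **worker is the positive class** (TP = correctly
#' detected workers, TN = correctly detected drones).  This is the opposite
#' of the intuitive "detect the drone" framing; metrics computed with the
#' classes swapped are not comparable.
#'
#' @param truth,predicted Character vectors of `"worker"`/`"drone"` labels
#'   of equal length.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_arg("truth and predicted must have the same length")
  }
  ok <- c("worker", "drone")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop_arg("labels must be 'worker' or 'drone'")
  }
  structure(list(tp = sum(truth == "worker" & predicted == "worker"),
                 tn = sum(truth == "drone" & predicted == "drone"),
                 fp = sum(truth == "drone" & predicted == "worker"),
                 fn = sum(truth == "worker" & predicted == "drone")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d TN=%d FP=%d FN=%d (worker = positive)\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A `confusion_counts` object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop_arg("no evaluated segments")
  (counts$tp + counts$tn) / total
}

#' F1 score
#'
#' `2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall for
#' the worker (positive) class.
#'
#' @param counts A `confusion_counts` object.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) stop_arg("F1 undefined: no positive-class instances or predictions")
  2 * counts$tp / den
}
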