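#' Extract a feature matrix from a list of segments
#'
#' Applies one of the four extractors to every segment and collects the
#' results into a `bee_features` object: a numeric matrix (one row per
#' segment) plus the labels, source ids and method tag.
#'
#' @param segments List of [bee_audio] segments.
#' @param method One of `"burg"`, `"music"`, `"mfcc"`, `"gtcc"`.
#' @param spectral A [spectral_config] (used for burg/music).
#' @param cepstral A [cepstral_config] (used for mfcc/gtcc).
#' @return A `bee_features` object with elements `values` (n x dim matrix),
#'   `method`, `labels`, `source_ids`.
#' @export
extract_features <- function(segments, method = c("burg", "music", "mfcc", "gtcc"),
                             spectral = spectral_config(),
                             cepstral = cepstral_config()) {
  method <- match.arg(method)
  if (length(segments) == 0) stop_arg("no segments to extract features from")
  rows <- lapply(segments, function(s) {
    switch(method,
           burg = spectral_features(s, "burg", spectral),
           music = spectral_features(s, "music", spectral),
           mfcc = mfcc(s, cepstral),
           gtcc = gtcc(s, cepstral))
  })
  values <- do.call(rbind, lapply(rows, as.numeric))
  if (!all(is.finite(values))) stop_arg("non-finite feature values produced")
  structure(list(values = values, method = method,
                 labels = vapply(segments, function(s) s$label, character(1)),
                 source_ids = vapply(segments, function(s) s$source_id, character(1))),
            class = "bee_features")
}

#' @export
print.bee_features <- function(x, ...) {
  cat(sprintf("<bee_features> %d segments x %d dims, method=%s (%s)\n",
              nrow(x$values), ncol(x$values), x$method,
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# Subset a feature set by row index, keeping metadata aligned.
subset_features <- function(x, idx) {
  structure(list(values = x$values[idx, , drop = FALSE], method = x$method,
                 labels = x$labels[idx], source_ids = x$source_ids[idx]),
            class = "bee_features")
}

#' Write a feature set to CSV
#'
#' One row per segment: `source_id`, `label`, `method`, then the feature
#' values `v1..vdim`.
#'
#' @param features A `bee_features` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "bee_features"))
  df <- data.frame(source_id = features$source_ids, label = features$labels,
                   method = features$method, features$values,
                   check.names = FALSE)
  names(df)[-(1:3)] <- paste0("v", seq_len(ncol(features$values)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature set written by [write_features]
#' @param path CSV path.
#' @return A `bee_features` object.
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  structure(list(values = as.matrix(df[, -(1:3), drop = FALSE]),
                 method = df$method[1], labels = df$label,
                 source_ids = df$source_id),
            class = "bee_features")
}
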