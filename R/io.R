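# Readers/writers for the package's external formats: multi-page TIFF for
# videos and movies, JSON sidecars for ground-truth traces, CSV for bout
# tables and feature matrices, RDS archives for trained classifiers.

#' Write a video or movie as multi-page 8-bit grayscale TIFF
#'
#' @param frames height x width x frames array (intensities 0-255), or a
#'   `rendered_video` / `fluorescence_movie`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(frames, path) {
  if (inherits(frames, "rendered_video") ||
      inherits(frames, "fluorescence_movie")) {
    frames <- frames$frames
  }
  pages <- lapply(seq_len(dim(frames)[3]), function(i) {
    m <- frames[, , i] / 255
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file.
#' @return height x width x frames array, intensities on 0-255.
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * 255
  arr
}

#' Write a tail trace as a JSON sidecar
#'
#' Schema: `frame_rate`, `tail_length_px`, `base`, and `points` — one list of
#' `[x, y]` pairs per frame, 0-based pixel coordinates, origin top-left.
#'
#' @param trace A `tail_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "tail_trace"))
  pts <- lapply(seq_len(n_frames(trace)), function(i) {
    unname(trace$points[i, , , drop = TRUE])
  })
  obj <- list(frame_rate = trace$frame_rate,
              tail_length_px = trace$tail_length_px,
              base = trace$base, points = pts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a tail trace from its JSON sidecar
#'
#' @param path JSON file written by [write_trace_json()].
#' @return A `tail_trace`.
#' @export
read_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.list(pts)) {
    arr <- array(NA_real_, dim = c(length(pts), nrow(pts[[1]]), 2),
                 dimnames = list(NULL, NULL, c("x", "y")))
    for (i in seq_along(pts)) arr[i, , ] <- as.matrix(pts[[i]])
  } else {
    arr <- aperm(pts, c(1, 2, 3))
    dimnames(arr) <- list(NULL, NULL, c("x", "y"))
  }
  new_tail_trace(arr, obj$frame_rate, obj$tail_length_px, obj$base)
}

#' Write / read a bout table CSV
#'
#' Columns `start_frame`, `end_frame` (half-open, 1-based) plus any extras
#' present (`class`, `label`, `trial_id`, ...).
#'
#' @param bouts data.frame.
#' @param path CSV file.
#' @return `path` / the data.frame.
#' @export
write_bout_csv <- function(bouts, path) {
  stopifnot(all(c("start_frame", "end_frame") %in% names(bouts)))
  write.csv(bouts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bout_csv
#' @export
read_bout_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_frame", "end_frame") %in% names(df))) {
    stopf("not a bout table: missing start_frame/end_frame columns")
  }
  df
}

#' Write / read a feature matrix CSV
#'
#' One row per bout: the 16 named feature columns, a `label` column, and any
#' provenance columns.
#'
#' @param data A [labeled_bout_set()].
#' @param path CSV file.
#' @return `path` / a `labeled_bout_set`.
#' @export
write_features_csv <- function(data, path) {
  stopifnot(inherits(data, "labeled_bout_set"))
  df <- cbind(data$features, label = as.character(data$labels))
  if (!is.null(data$provenance)) df <- cbind(df, data$provenance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stopf("feature CSV lacks a label column")
  extra <- setdiff(names(df), c(feature_names(), "label"))
  labeled_bout_set(df[feature_names()], df$label,
                   provenance = if (length(extra)) df[extra])
}

#' Save / load a trained bout classifier
#'
#' The archive records a schema version that is checked on load, so stale
#' model files fail loudly rather than silently misclassifying.
#'
#' @param clf A `bout_classifier`.
#' @param path Output file (RDS archive).
#' @return `path` / the classifier.
#' @export
save_bout_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "bout_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_bout_classifier
#' @export
load_bout_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "bout_classifier") ||
      !identical(clf$schema, classifier_schema())) {
    stopf("file is not a compatible classifier archive (schema %s expected)",
          classifier_schema())
  }
  clf
}
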