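#' Names of the 16 per-bout kinematic parameters
#'
#' @return Character vector of the 16 feature names in canonical order. The
#'   first five are the virtual-prey classifier's feature set; the first six
#'   are used for prey presented as live paramecia.
#' @export
feature_names <- function() {
  c("f1_max_tail_curvature", "f2_n_peaks_tail_angle", "f3_mean_tip_angle",
    "f4_max_tail_angle", "f5_mean_tip_position",
    "f6_mean_frames_between_peaks", "f7_med_freq_power", "f8_low_freq_power",
    "f9_tail_vs_tip_angle", "f10_tail_vs_tip_angle_at_max",
    "f11_var_tail_angle", "f12_mean_tail_curvature", "f13_mean_tail_tip_angle",
    "f14_mean_tail_position", "f15_mean_curvature_vs_tail_angle",
    "f16_max_tip_horizontal_deviation")
}

#' Detect peaks in a 1-D signal
#'
#' Local maxima strictly greater than both neighbours, with plateaus taking
#' the leftmost index, filtered by topographic prominence (a peak must rise
#' at least `min_prominence` above the higher of the two valleys separating
#' it from higher ground).
#'
#' @param signal Numeric vector (>= 3 samples).
#' @param min_prominence Prominence floor; 0 keeps every strict maximum.
#' @return Integer vector of peak indices.
#' @export
detect_peaks <- function(signal, min_prominence = 0) {
  n <- length(signal)
  if (n < 3) stopf("need at least 3 samples")
  if (anyNA(signal)) signal <- approx(seq_len(n), signal, seq_len(n),
                                      rule = 2)$y
  # collapse plateaus, remembering the leftmost index of each run
  r <- rle(signal)
  vals <- r$values
  firsts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  m <- length(vals)
  if (m < 3) return(integer(0))
  core <- 2:(m - 1)
  is_peak <- vals[core] > vals[core - 1] & vals[core] > vals[core + 1]
  peaks <- firsts[core][is_peak]
  if (!length(peaks) || min_prominence <= 0) return(peaks)
  keep <- vapply(peaks, function(p) {
    peak_prominence(signal, p) >= min_prominence
  }, logical(1))
  peaks[keep]
}

peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  i <- p
  while (i > 1) {
    i <- i - 1
    if (x[i] > x[p]) break
    left_min <- min(left_min, x[i])
  }
  if (i == 1 && x[1] <= x[p]) left_min <- min(left_min, min(x[1:p]))
  right_min <- x[p]
  i <- p
  while (i < n) {
    i <- i + 1
    if (x[i] > x[p]) break
    right_min <- min(right_min, x[i])
  }
  x[p] - max(left_min, right_min)
}

#' Spectral power of a signal in a frequency band
#'
#' Mean-removed discrete Fourier transform; power is the summed one-sided
#' squared magnitude over bins falling inside `band`, normalized so a unit
#' sinusoid whose frequency sits on a bin contributes its variance (1/2).
#'
#' @param signal Numeric vector (>= 8 samples).
#' @param frame_rate Sampling rate in frames/s.
#' @param band `c(low, high)` in Hz; must lie within (0, Nyquist].
#' @return Power (signal-variance units).
#' @export
band_power <- function(signal, frame_rate, band) {
  n <- length(signal)
  if (n < 8) stopf("need at least 8 samples")
  if (band[1] < 0 || band[2] > frame_rate / 2 || band[1] >= band[2]) {
    stopf("band [%g, %g] Hz is invalid for Nyquist %g Hz",
          band[1], band[2], frame_rate / 2)
  }
  if (anyNA(signal)) signal <- approx(seq_len(n), signal, seq_len(n),
                                      rule = 2)$y
  x <- signal - mean(signal)
  X <- fft(x)
  k <- 0:(n - 1)
  freq <- k * frame_rate / n
  sel <- freq >= band[1] & freq <= band[2] & k <= n / 2 & k > 0
  2 * sum(Mod(X[sel])^2) / n^2
}

#' Extract the 16 per-bout kinematic parameters
#'
#' Computes the full feature vector for one bout of a kinematic series,
#' following the published parameter definitions: maxima and means over the
#' bout, the absolute tip angle for the mean tip angle, positions as
#' horizontal deflections in fractions of tail length, signed mean
#' differences for the tail-vs-tip comparisons, and the tail-vs-tip angle
#' difference evaluated at the frame of maximum absolute tail angle. Peak
#' counting uses the rectified tail angle (left and right beats both count).
#' `f6` (mean frames between peaks) is `NA` for bouts with fewer than two
#' peaks and is median-imputed at classification time.
#'
#' @param series A `kinematic_series`.
#' @param bout Bout interval (half-open), at least 4 frames.
#' @param low_band,mid_band Frequency bands in Hz for the spectral features.
#' @param peak_floor Prominence floor (degrees) for tail-angle peaks.
#' @return Named numeric vector of length 16.
#' @export
extract_features <- function(series, bout, low_band = c(0.5, 5),
                             mid_band = c(5, 30), peak_floor = 2) {
  idx <- bout_frames(series, bout)
  if (length(idx) < 4) stopf("bout too short: %d frames (< 4)", length(idx))
  ta <- series$tail_angle[idx]
  tip <- series$tip_angle[idx]
  tca <- series$tip_com_angle[idx]
  tpos <- series$tip_position[idx]
  tdef <- series$tip_deflection[idx]
  t12 <- series$tail_position_12plus[idx]
  curv <- series$curvature[idx]
  ok <- complete.cases(ta, tip, tca, tpos, tdef, t12, curv)
  if (sum(ok) < 4) stopf("bout has fewer than 4 usable frames")
  peaks <- detect_peaks(abs(ifelse(is.na(ta), 0, ta)),
                        min_prominence = peak_floor)
  f2 <- length(peaks)
  imax <- idx[ok][which.max(abs(ta[ok]))] - idx[1] + 1L
  out <- c(
    f1_max_tail_curvature = max(curv[ok]),
    f2_n_peaks_tail_angle = as.numeric(f2),
    f3_mean_tip_angle = mean(abs(tip[ok])),
    f4_max_tail_angle = max(abs(ta[ok])),
    f5_mean_tip_position = abs(mean(tpos[ok])),
    f6_mean_frames_between_peaks =
      if (f2 >= 2) mean(diff(peaks)) else NA_real_,
    f7_med_freq_power = band_power(ta[ok], series$frame_rate, mid_band),
    f8_low_freq_power = band_power(ta[ok], series$frame_rate, low_band),
    f9_tail_vs_tip_angle = mean(ta[ok] - tca[ok]),
    f10_tail_vs_tip_angle_at_max = ta[imax] - tca[imax],
    f11_var_tail_angle = var(ta[ok]),
    f12_mean_tail_curvature = mean(curv[ok]),
    f13_mean_tail_tip_angle = abs(mean(tip[ok])),
    f14_mean_tail_position = mean(t12[ok]),
    f15_mean_curvature_vs_tail_angle = mean(curv[ok] - ta[ok]),
    f16_max_tip_horizontal_deviation = max(abs(tdef[ok])))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Bundle feature vectors with class labels
#'
#' @param features data.frame (or matrix) with the 16 feature columns.
#' @param labels Factor or character vector of `"prey_capture"` /
#'   `"spontaneous"` labels, one per row.
#' @param provenance Optional data.frame of trial/bout identifiers.
#' @return A `labeled_bout_set`.
#' @export
labeled_bout_set <- function(features, labels, provenance = NULL) {
  features <- as.data.frame(features)
  missing_cols <- setdiff(feature_names(), names(features))
  if (length(missing_cols)) {
    stopf("features are missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  features <- features[feature_names()]
  labels <- factor(labels, levels = c("prey_capture", "spontaneous"))
  if (anyNA(labels)) stopf("labels must be 'prey_capture' or 'spontaneous'")
  if (nrow(features) != length(labels)) {
    stopf("features (%d rows) and labels (%d) differ in length",
          nrow(features), length(labels))
  }
  structure(list(features = features, labels = labels,
                 provenance = provenance),
            class = "labeled_bout_set")
}

#' @export
print.labeled_bout_set <- function(x, ...) {
  cat(sprintf("<labeled_bout_set> %d bouts (%s)\n", nrow(x$features),
              paste(sprintf("%s: %d", levels(x$labels),
                            tabulate(x$labels, 2)), collapse = ", ")))
  invisible(x)
}

#' Synthesize an expert-labeled bout set
#'
#' Generates ground-truth bouts of the prey-capture classes (a mixture of
#' forward swims and j-turns) and spontaneous swims, computes their
#' kinematics and the 16 parameters, and returns a labeled training set.
#' Defaults reproduce the published training design: 248 prey-capture and
#' 121 spontaneous bouts.
#'
#' @param n_prey,n_spontaneous Bout counts per class.
#' @param j_turn_fraction Fraction of prey bouts generated as j-turns.
#' @param frame_rate Frames per second.
#' @param seed Integer master seed.
#' @param ... Passed to [sample_bout_params()].
#' @return A [labeled_bout_set()].
#' @export
synthesize_labeled_bouts <- function(n_prey = 248, n_spontaneous = 121,
                                     j_turn_fraction = 0.3, frame_rate = 300,
                                     seed = 1, ...) {
  n_j <- round(n_prey * j_turn_fraction)
  n_fwd <- n_prey - n_j
  params <- c(
    sample_bout_params("prey_forward", n_fwd, seed = derive_seed(seed, 1),
                       ...),
    sample_bout_params("j_turn", n_j, seed = derive_seed(seed, 2), ...),
    sample_bout_params("spontaneous", n_spontaneous,
                       seed = derive_seed(seed, 3), ...))
  labels <- rep(c("prey_capture", "spontaneous"),
                c(n_prey, n_spontaneous))
  geometry <- tail_geometry()
  rows <- lapply(seq_along(params), function(i) {
    tr <- generate_bout(params[[i]], frame_rate = frame_rate,
                        seed = derive_seed(seed, 100 + i),
                        geometry = geometry)
    ks <- compute_kinematics(tr, rest_axis = geometry$heading)
    extract_features(ks, c(1L, n_frames(tr) + 1L))
  })
  feats <- as.data.frame(do.call(rbind, rows))
  labeled_bout_set(feats, labels,
                   provenance = data.frame(
                     bout_id = seq_along(params),
                     class = vapply(params, `[[`, "", "behavior_class")))
}
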