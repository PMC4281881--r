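#' Calibrate the tail tracker from the first video frame
#'
#' Characterizes the width and contrast of the tail at the user-supplied base
#' point and derives everything the per-frame tracker needs: a Gaussian
#' smoothing kernel and a matched tail-profile kernel sized to the measured
#' width, the end-of-tail luminance-change threshold (a fraction of the
#' measured contrast), and a step size chosen so a full tail yields
#' approximately `target_points` midpoints.
#'
#' @param frame 2-D numeric matrix (height x width), row = y, column = x.
#' @param base_point `c(x, y)` 0-based pixel position of the tail base; must
#'   lie on the tail (intensity well above background).
#' @param heading Initial tracking direction (unit vector), default caudal =
#'   image-down.
#' @param target_points Desired number of midpoints over the full tail.
#' @param stop_frac End-of-tail threshold as a fraction of the calibrated
#'   contrast (the luminance change across a slice below which tracking
#'   stops).
#' @return A `tracker_calibration` list: `tail_width_px`, `tail_contrast`,
#'   `step_px`, `kernel`, `smooth_kernel`, `luminance_change_threshold`,
#'   `background`, `heading`, `half_slice`, `max_points`.
#' @export
calibrate_tracker <- function(frame, base_point, heading = c(0, 1),
                              target_points = 40, stop_frac = 0.3) {
  stopifnot(is.matrix(frame))
  bg <- median(frame)
  spread <- mad(frame)
  base_val <- bilinear_sample(frame, base_point[1], base_point[2])
  floor_margin <- max(6 * spread, 0.05 * (max(frame) - bg), 1e-8)
  if (!is.finite(base_val) || base_val < bg + floor_margin) {
    stopf(paste("calibration failure: base point intensity %.2f is not",
                "above background %.2f"), base_val, bg)
  }
  heading <- heading / sqrt(sum(heading^2))
  perp <- c(heading[2], -heading[1])
  offs <- seq(-10, 10, by = 0.5)
  prof <- bilinear_sample(frame,
                          base_point[1] + offs * perp[1],
                          base_point[2] + offs * perp[2])
  peak <- max(prof, na.rm = TRUE)
  contrast <- peak - bg
  width <- profile_fwhm(offs, prof, bg)
  sigma_smooth <- max(width / 2, 0.6)
  sigma_kernel <- max(width / (2 * sqrt(2 * log(2))), 0.5)
  smooth_kernel <- gaussian_kernel(sigma_smooth)
  kernel <- gaussian_kernel(sigma_kernel)
  half_slice <- max(4L, as.integer(round(2 * width)))
  threshold <- stop_frac * contrast
  # provisional walk along the tail to measure its length, then choose the
  # step so the full tail yields ~target_points points
  prov <- cpp_track_frame(frame, base_point[1], base_point[2],
                          heading[1], heading[2], max(2, width),
                          smooth_kernel, kernel, half_slice, threshold,
                          3L * target_points, bg, bg + 0.7 * contrast)
  if (nrow(prov) < 5) {
    stopf("calibration failure: could not follow the tail from the base")
  }
  len <- arc_length(prov)
  step <- len / (target_points - 1)
  structure(list(tail_width_px = width, tail_contrast = contrast,
                 step_px = step, kernel = kernel,
                 smooth_kernel = smooth_kernel,
                 luminance_change_threshold = threshold,
                 background = bg, heading = heading,
                 half_slice = half_slice,
                 max_points = as.integer(ceiling(1.6 * target_points)),
                 target_points = as.integer(target_points)),
            class = "tracker_calibration")
}

# FWHM of an intensity profile above background, with linear interpolation of
# the half-maximum crossings around the peak.
profile_fwhm <- function(offs, prof, bg) {
  prof <- prof - bg
  pk <- which.max(prof)
  half <- prof[pk] / 2
  left <- pk
  while (left > 1 && prof[left - 1] > half) left <- left - 1
  right <- pk
  n <- length(prof)
  while (right < n && prof[right + 1] > half) right <- right + 1
  x_left <- if (left > 1) {
    approx(prof[c(left - 1, left)], offs[c(left - 1, left)], xout = half)$y
  } else offs[left]
  x_right <- if (right < n) {
    approx(prof[c(right + 1, right)], offs[c(right + 1, right)],
           xout = half)$y
  } else offs[right]
  max(x_right - x_left, 1)
}

# Vectorized bilinear interpolation at 0-based (x, y) pixel coordinates.
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(x))
  ok <- x >= 0 & y >= 0 & x <= W - 1 & y <= H - 1 & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * H
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i00 + H]) +
    fy * ((1 - fx) * img[i00 + 1] + fx * img[i00 + H + 1])
  out[ok] <- v
  out
}

#' Track the tail in a single frame
#'
#' Iterates from the base point: the next midpoint is predicted by linear
#' extrapolation of the previous segment, an intensity slice is sampled
#' perpendicular to the predicted direction (bilinear interpolation, 1 px
#' spacing, length about four tail widths), smoothed, convolved with the
#' calibrated tail-profile kernel, and the (sub-pixel refined) maximum taken
#' as the midpoint. Tracking stops when the luminance change across the
#' slice falls below the calibrated threshold.
#'
#' @param frame 2-D numeric matrix.
#' @param base_point `c(x, y)` 0-based tail-base position.
#' @param calibration A [calibrate_tracker()] result.
#' @return n x 2 matrix of 0-based (x, y) midpoints from base to tip, with
#'   attribute `flagged = TRUE` when fewer than 10 points were found.
#' @export
track_frame <- function(frame, base_point, calibration) {
  stopifnot(inherits(calibration, "tracker_calibration"))
  pts <- cpp_track_frame(frame, base_point[1], base_point[2],
                         calibration$heading[1], calibration$heading[2],
                         calibration$step_px, calibration$smooth_kernel,
                         calibration$kernel, calibration$half_slice,
                         calibration$luminance_change_threshold,
                         calibration$max_points, calibration$background,
                         calibration$background + 0.7 * calibration$tail_contrast)
  pts <- smooth_polyline(pts)
  attr(pts, "flagged") <- nrow(pts) < 10
  pts
}

# Light 3-point smoothing of a tracked polyline; endpoints (base and tip)
# are kept exact so the measured tail length is not biased.
smooth_polyline <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  mid <- 2:(n - 1)
  out <- pts
  out[mid, ] <- (pts[mid - 1, ] + pts[mid, ] + pts[mid + 1, ]) / 3
  out
}

#' Digitize the tail across a whole video
#'
#' Calibrates on the first frame, tracks every frame, and resamples each
#' frame's midpoints to exactly `target_points` points equally spaced in arc
#' length (fixed feature dimensions downstream). Frames where tracking finds
#' fewer than 10 points are flagged and carried as missing values; the video
#' is rejected if more than `fail_tolerance` of frames are flagged.
#'
#' @param frames height x width x n array, or a list of matrices, or a
#'   `rendered_video`.
#' @param base_point `c(x, y)` 0-based tail-base position (fixed across
#'   frames; head-embedded preparation).
#' @param frame_rate Frames per second of the recording.
#' @param heading Initial tracking direction.
#' @param target_points Points per frame after resampling.
#' @param fail_tolerance Maximum tolerated fraction of flagged frames.
#' @param calibration Optional pre-computed [calibrate_tracker()] result.
#' @return A `tail_trace` (flagged frames have `NA` points and
#'   `trace$flags` set).
#' @export
track_video <- function(frames, base_point, frame_rate = 300,
                        heading = c(0, 1), target_points = 40,
                        fail_tolerance = 0.1, calibration = NULL) {
  if (inherits(frames, "rendered_video")) frames <- frames$frames
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  n <- length(frames)
  if (n < 1) stopf("need at least one frame")
  if (is.null(calibration)) {
    calibration <- calibrate_tracker(frames[[1]], base_point, heading,
                                     target_points)
  }
  pts <- array(NA_real_, dim = c(n, target_points, 2),
               dimnames = list(NULL, NULL, c("x", "y")))
  flags <- logical(n)
  lengths <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- track_frame(frames[[i]], base_point, calibration)
    if (attr(p, "flagged")) {
      flags[i] <- TRUE
      next
    }
    lengths[i] <- arc_length(p)
    pts[i, , ] <- resample_polyline(p, target_points)
  }
  # resting arc length: the median over frames is robust to the slight
  # lengthening of strongly bent frames and to per-frame tip jitter
  tail_length <- median(lengths, na.rm = TRUE)
  if (mean(flags) > fail_tolerance) {
    stopf("video quality error: %.0f%% of frames failed tracking (> %.0f%%)",
          100 * mean(flags), 100 * fail_tolerance)
  }
  new_tail_trace(pts, frame_rate, tail_length, as.numeric(base_point),
                 rest_axis = NULL, flags = flags)
}
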