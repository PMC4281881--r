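#' Per-frame kinematic signals from a tail trace
#'
#' Converts a digitized tail into the signals the bout features are built
#' from. Angles are signed in degrees (rightward of the rest axis positive):
#' `tail_angle` is the deflection of the tail's center of mass from the rest
#' axis; `tip_angle` the angle of a line fit through the last `tip_points`
#' points relative to the rest axis; `tip_com_angle` the deflection angle of
#' the centroid of those points. Positions are horizontal (lateral)
#' deflections as fractions of tail length: `tip_position` for the last
#' `tip_points` points' centroid, `tip_deflection` for the distal tail
#' point, `tail_position_12plus` for points 12 to the end. `curvature` is
#' the per-frame maximum absolute discrete curvature (three-point
#' circumscribed circle on lightly smoothed points) in units of 1/tail
#' length. Flagged or degenerate frames carry `NA` in every signal.
#'
#' @param trace A `tail_trace`.
#' @param rest_axis Optional unit vector of the resting tail direction. When
#'   `NULL` it is estimated as the base-to-tip line of the frame whose
#'   base-to-tip angle is the median over frames (a resting frame in any
#'   trial containing rest). Pass it explicitly for bout-only traces.
#' @param tip_points Number of distal points defining the tail tip (8, as in
#'   the feature definitions).
#' @param point_smooth Moving-average window (points) applied along the tail
#'   before curvature estimation.
#' @param curvature_stencil Half-width (in points) of the three-point
#'   curvature stencil; default one tenth of the point count.
#' @return A `kinematic_series` list of equal-length per-frame signals plus
#'   `frame_rate`, `tail_length_px`, `rest_axis`, `flags`.
#' @export
compute_kinematics <- function(trace, rest_axis = NULL, tip_points = 8,
                               point_smooth = 5, curvature_stencil = NULL) {
  stopifnot(inherits(trace, "tail_trace"))
  pts <- trace$points
  n <- dim(pts)[1]
  P <- dim(pts)[2]
  if (P < 10) stopf("need at least 10 points per frame, got %d", P)
  x <- pts[, , 1, drop = TRUE]
  y <- pts[, , 2, drop = TRUE]
  if (n == 1L) { x <- matrix(x, 1); y <- matrix(y, 1) }
  flags <- trace$flags | !is.finite(rowSums(x) + rowSums(y))
  base <- trace$base %||% c(median(x[!flags, 1]), median(y[!flags, 1]))
  if (is.null(rest_axis)) {
    ok <- which(!flags)
    if (!length(ok)) stopf("all frames are flagged; cannot estimate rest axis")
    vx <- x[ok, P] - base[1]
    vy <- y[ok, P] - base[2]
    ang <- atan2(vx, vy)
    med <- ok[which.min(abs(ang - median(ang)))]
    rest_axis <- c(x[med, P] - base[1], y[med, P] - base[2])
  }
  rest_axis <- rest_axis / sqrt(sum(rest_axis^2))
  perp <- c(rest_axis[2], -rest_axis[1])  # rightward-positive
  L <- trace$tail_length_px
  u <- (x - base[1]) * perp[1] + (y - base[2]) * perp[2]    # lateral, px
  a <- (x - base[1]) * rest_axis[1] + (y - base[2]) * rest_axis[2]
  deg <- 180 / pi
  tail_angle <- atan2(rowMeans(u), rowMeans(a)) * deg
  tip_idx <- (P - tip_points + 1):P
  tu <- u[, tip_idx, drop = FALSE]
  ta <- a[, tip_idx, drop = FALSE]
  mu_u <- rowMeans(tu)
  mu_a <- rowMeans(ta)
  cov_au <- rowMeans(ta * tu) - mu_a * mu_u
  var_a <- rowMeans(ta * ta) - mu_a * mu_a
  tip_angle <- ifelse(var_a > 1e-12, atan(cov_au / var_a) * deg,
                      sign(cov_au) * 90)
  tip_com_angle <- atan2(mu_u, mu_a) * deg
  tip_position <- mu_u / L
  tip_deflection <- u[, P] / L
  tail_position_12plus <- rowMeans(u[, 12:P, drop = FALSE]) / L
  curvature <- max_abs_curvature(x, y, point_smooth, curvature_stencil) * L
  out <- list(tail_angle = tail_angle, tip_angle = tip_angle,
              tip_com_angle = tip_com_angle, tip_position = tip_position,
              tip_deflection = tip_deflection,
              tail_position_12plus = tail_position_12plus,
              curvature = curvature, frame_rate = trace$frame_rate,
              tail_length_px = L, rest_axis = rest_axis, flags = flags)
  for (nm in c("tail_angle", "tip_angle", "tip_com_angle", "tip_position",
               "tip_deflection", "tail_position_12plus", "curvature")) {
    out[[nm]][flags] <- NA_real_
  }
  structure(out, class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d frames at %g f/s (%d flagged)\n",
              length(x$tail_angle), x$frame_rate, sum(x$flags)))
  invisible(x)
}

# Smooth a T x P matrix along the point dimension with a clamped-index
# moving average.
smooth_along_points <- function(m, window) {
  if (window <= 1) return(m)
  P <- ncol(m)
  hw <- window %/% 2
  out <- 0
  cnt <- 0
  for (o in (-hw):(window - hw - 1)) {
    idx <- pmin(pmax(seq_len(P) + o, 1L), P)
    out <- out + m[, idx, drop = FALSE]
    cnt <- cnt + 1
  }
  out / cnt
}

# Per-frame maximum absolute Menger curvature (1/px) over a symmetric
# stencil, on smoothed points.
max_abs_curvature <- function(x, y, point_smooth, stencil = NULL) {
  P <- ncol(x)
  k <- stencil %||% max(1L, round(P / 10))
  xs <- smooth_along_points(x, point_smooth)
  ys <- smooth_along_points(y, point_smooth)
  i <- (k + 1):(P - k)
  ax <- xs[, i - k, drop = FALSE]; ay <- ys[, i - k, drop = FALSE]
  bx <- xs[, i, drop = FALSE];     by <- ys[, i, drop = FALSE]
  cx <- xs[, i + k, drop = FALSE]; cy <- ys[, i + k, drop = FALSE]
  cross <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- sqrt((bx - ax)^2 + (by - ay)^2)
  d2 <- sqrt((cx - bx)^2 + (cy - by)^2)
  d3 <- sqrt((cx - ax)^2 + (cy - ay)^2)
  kappa <- abs(2 * cross / (d1 * d2 * d3))
  kappa[!is.finite(kappa)] <- 0
  apply(kappa, 1, max)
}

as_bout <- function(bout) {
  if (is.data.frame(bout)) {
    stopifnot(nrow(bout) == 1)
    bout <- c(bout$start_frame, bout$end_frame)
  }
  if (is.list(bout)) bout <- c(bout$start_frame, bout$end_frame)
  bout <- as.integer(bout[1:2])
  if (bout[1] >= bout[2]) stopf("bout must satisfy start_frame < end_frame")
  bout
}

bout_frames <- function(series, bout) {
  b <- as_bout(bout)
  if (b[1] < 1 || b[2] > length(series$tail_angle) + 1L) {
    stopf("bout [%d, %d) lies outside the series (%d frames)",
          b[1], b[2], length(series$tail_angle))
  }
  seq.int(b[1], b[2] - 1L)
}

#' Segment swim bouts from a kinematic series
#'
#' Bouts are extracted with a threshold on the normalized, smoothed first
#' derivative of the tail bend angle: the derivative of `tail_angle` is
#' moving-average smoothed, scaled by its median absolute deviation (robust
#' to bout-heavy trials), and frames exceeding `threshold` scale units are
#' marked active; active runs separated by fewer than `min_gap` inactive
#' frames are merged and runs shorter than `min_duration` dropped. The same
#' operation serves swim counting in optomotor assays.
#'
#' @param series A [compute_kinematics()] result.
#' @param smooth_window Moving-average window in frames.
#' @param threshold Activity threshold in robust scale units.
#' @param min_gap Gaps shorter than this many frames are closed.
#' @param min_duration Minimum bout length in frames.
#' @return data.frame with `start_frame`, `end_frame` (half-open, 1-based).
#' @export
segment_bouts <- function(series, smooth_window = 5, threshold = 3.5,
                          min_gap = 15, min_duration = 10) {
  stopifnot(inherits(series, "kinematic_series"))
  x <- series$tail_angle
  n <- length(x)
  if (n <= smooth_window) stopf("series shorter than the smoothing window")
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0))
  if (all(is.na(x))) {
    warnf("all frames missing; no bouts")
    return(empty)
  }
  # missing frames are bridged by linear interpolation for segmentation only
  if (anyNA(x)) {
    x <- approx(seq_len(n), x, xout = seq_len(n), rule = 2)$y
  }
  d <- c(0, diff(x))
  ds <- moving_average(d, smooth_window)
  scale <- mad(ds)
  if (scale == 0) scale <- sd(ds)
  if (!is.finite(scale) || scale == 0) return(empty)
  active <- abs(ds / scale) > threshold
  r <- rle(active)
  # close short inactive gaps between active runs
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    r$values[interior][!r$values[interior] &
                         r$lengths[interior] < min_gap] <- TRUE
  }
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  data.frame(start_frame = starts[keep], end_frame = ends[keep] + 1L)
}

#' Duration of the longest sustained tail bend in a bout
#'
#' Longest run of consecutive frames whose absolute tail angle exceeds
#' `angle_threshold`, in milliseconds. The distribution of this statistic
#' over spontaneous bouts peaks at ~27 ms (one beat half-cycle), while
#' j-turns produce a long-duration shoulder of sustained bends.
#'
#' @param series A `kinematic_series`.
#' @param bout Bout as `c(start_frame, end_frame)` (half-open) or a one-row
#'   bout-table data.frame.
#' @param angle_threshold Bend threshold in degrees (default 20).
#' @return Duration in ms (0 when the angle never exceeds the threshold).
#' @export
longest_bend_duration <- function(series, bout, angle_threshold = 20) {
  idx <- bout_frames(series, bout)
  over <- abs(series$tail_angle[idx]) > angle_threshold
  over[is.na(over)] <- FALSE
  r <- rle(over)
  runs <- r$lengths[r$values]
  if (!length(runs)) return(0)
  max(runs) * 1000 / series$frame_rate
}

#' Mean tail-beat amplitude of a bout
#'
#' Mean peak-to-trough half-amplitude of the tail-tip deflection over the
#' bout's oscillation cycles (alternating extrema with hysteresis; adjacent
#' peak/trough pairs averaged), as a fraction of tail length. Bouts with a
#' single sustained deflection (j-turns) fall back to the maximum absolute
#' deflection.
#'
#' @param series A `kinematic_series`.
#' @param bout Bout interval (half-open).
#' @param min_swing_frac Hysteresis for extrema detection, as a fraction of
#'   the bout's deflection range.
#' @return Amplitude as a fraction of tail length.
#' @export
bout_amplitude <- function(series, bout, min_swing_frac = 0.25) {
  idx <- bout_frames(series, bout)
  x <- series$tip_deflection[idx]
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  rng <- diff(range(x))
  if (rng == 0) return(0)
  ext <- alternating_extrema(x, min_swing_frac * rng)
  if (length(ext) < 2) return(max(abs(x)))
  mean(abs(diff(x[ext])) / 2)
}
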