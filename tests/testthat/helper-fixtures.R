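# Fixtures built in code: hand-constructed traces and kinematic series used
# across the unit tests.

# A kinematic_series with hand-chosen signals (everything defaulting to 0).
make_series <- function(n, frame_rate = 300, tail_angle = rep(0, n),
                        tip_angle = rep(0, n), tip_com_angle = rep(0, n),
                        tip_position = rep(0, n),
                        tip_deflection = rep(0, n),
                        tail_position_12plus = rep(0, n),
                        curvature = rep(0, n)) {
  structure(list(tail_angle = tail_angle, tip_angle = tip_angle,
                 tip_com_angle = tip_com_angle, tip_position = tip_position,
                 tip_deflection = tip_deflection,
                 tail_position_12plus = tail_position_12plus,
                 curvature = curvature, frame_rate = frame_rate,
                 tail_length_px = 160, rest_axis = c(0, 1),
                 flags = rep(FALSE, n)),
            class = "kinematic_series")
}

# Trace whose every frame is the same polyline (n_points x 2).
static_trace <- function(polyline, n_frames = 3, frame_rate = 300,
                         base = polyline[1, ]) {
  P <- nrow(polyline)
  pts <- array(NA_real_, dim = c(n_frames, P, 2),
               dimnames = list(NULL, NULL, c("x", "y")))
  for (i in seq_len(n_frames)) pts[i, , ] <- polyline
  structure(list(points = pts, frame_rate = frame_rate,
                 tail_length_px = sum(sqrt(rowSums(diff(polyline)^2))),
                 base = base, rest_axis = NULL,
                 flags = rep(FALSE, n_frames)),
            class = "tail_trace")
}

# Straight vertical tail polyline (like a resting larva).
straight_polyline <- function(n_points = 40, base = c(150, 60),
                              length_px = 160) {
  s <- seq(0, 1, length.out = n_points)
  cbind(base[1], base[2] + s * length_px)
}

# Tail bent as a circular arc of known radius, starting at `base` heading
# down; subtends length_px of arc.
arc_polyline <- function(radius, n_points = 40, base = c(150, 60),
                         length_px = 160) {
  theta <- seq(0, length_px / radius, length.out = n_points)
  cbind(base[1] + radius * (1 - cos(theta)), base[2] + radius * sin(theta))
}

# Horizontal mirror of a trace about the image midline (0-based width W).
mirror_trace <- function(trace, width = 300) {
  out <- trace
  out$points[, , 1] <- (width - 1) - trace$points[, , 1]
  out$base[1] <- (width - 1) - trace$base[1]
  if (!is.null(out$rest_axis)) out$rest_axis[1] <- -out$rest_axis[1]
  out
}

# Feature data.frame of zeros with one named column substituted.
blank_features <- function(n, ...) {
  df <- as.data.frame(matrix(0, n, 16))
  names(df) <- feature_names()
  subs <- list(...)
  for (nm in names(subs)) df[[nm]] <- subs[[nm]]
  df
}
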