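#' Tail and imaging geometry for the synthetic generator
#'
#' Defaults mirror the behavioral recording configuration: 300 x 300 px
#' frames with the larva head-embedded at the top of the frame and the free
#' tail, about 160 px long, pointing down (caudal = image-down). Coordinates
#' are 0-based pixels, origin top-left, x rightward, y downward.
#'
#' @param base Tail-base pixel position `c(x, y)`.
#' @param length_px Rest tail length in pixels (base-to-tip arc length).
#' @param heading Unit vector of the resting tail direction.
#' @param dims Frame size `c(height, width)` in pixels.
#' @return A list with class `"tail_geometry"`.
#' @export
tail_geometry <- function(base = c(150, 60), length_px = 160,
                          heading = c(0, 1), dims = c(300, 300)) {
  heading <- heading / sqrt(sum(heading^2))
  structure(list(base = as.numeric(base), length_px = length_px,
                 heading = as.numeric(heading), dims = as.integer(dims)),
            class = "tail_geometry")
}

#' Kinematic parameters for one synthetic swim bout
#'
#' Bundles the ground-truth kinematics of a single bout of one of the three
#' behavior classes seen in the head-fixed assay: low-amplitude prey-capture
#' forward swims, sustained unilateral j-turns, and high-amplitude
#' spontaneous swims. Class defaults are anchored to the published bout
#' statistics: mean tail-beat amplitude 17% of tail length for prey-capture
#' forward swims vs 48% for spontaneous swims, and a spontaneous beat period
#' calibrated so the longest tail bend exceeding 20 degrees lasts about
#' 27 ms (see the methods vignette for the calibration).
#'
#' @param behavior_class `"prey_forward"`, `"j_turn"` or `"spontaneous"`.
#' @param tip_amplitude Peak horizontal tail-tip deflection as a fraction of
#'   tail length. Zero produces a straight tail (degenerate but allowed).
#' @param beat_frequency Tail-beat frequency in Hz (oscillatory classes).
#' @param bout_duration Bout duration in ms. For j-turns this is derived as
#'   `2 * ramp_duration + hold_duration` and need not be supplied.
#' @param hold_duration Sustained-bend time in ms; j-turns only.
#' @param hold_angle Tip angle in degrees held during a j-turn (sign sets the
#'   turn side).
#' @param noise_sd Per-point coordinate jitter, as a fraction of tail length.
#' @param ramp_duration j-turn bend/release ramp time in ms.
#' @return A list with class `"kinematics_params"`.
#' @export
kinematics_params <- function(behavior_class = c("prey_forward", "j_turn",
                                                 "spontaneous"),
                              tip_amplitude = NULL, beat_frequency = NULL,
                              bout_duration = NULL, hold_duration = NULL,
                              hold_angle = NULL, noise_sd = 0.005,
                              ramp_duration = 80) {
  behavior_class <- match.arg(behavior_class)
  defaults <- switch(behavior_class,
    prey_forward = list(tip_amplitude = 0.17, beat_frequency = 15,
                        bout_duration = 180, hold_duration = 0,
                        hold_angle = 0),
    spontaneous = list(tip_amplitude = 0.48, beat_frequency = 8.6,
                       bout_duration = 280, hold_duration = 0,
                       hold_angle = 0),
    j_turn = list(tip_amplitude = NA_real_, beat_frequency = 1,
                  bout_duration = NA_real_, hold_duration = 300,
                  hold_angle = 45))
  p <- list(
    behavior_class = behavior_class,
    tip_amplitude = tip_amplitude %||% defaults$tip_amplitude,
    beat_frequency = beat_frequency %||% defaults$beat_frequency,
    bout_duration = bout_duration %||% defaults$bout_duration,
    hold_duration = hold_duration %||% defaults$hold_duration,
    hold_angle = hold_angle %||% defaults$hold_angle,
    noise_sd = noise_sd,
    ramp_duration = ramp_duration)
  if (behavior_class == "j_turn") {
    # tip deflection that realizes the held tip angle for the s^1.5 bend
    # profile (tip slope = 1.5 * amplitude)
    if (is.na(p$tip_amplitude)) {
      p$tip_amplitude <- tan(abs(p$hold_angle) * pi / 180) / 1.5
    }
    if (is.na(p$bout_duration)) {
      p$bout_duration <- 2 * p$ramp_duration + p$hold_duration
    }
    if (p$hold_duration <= 0) stopf("j_turn requires hold_duration > 0")
  } else {
    if (p$hold_duration != 0) {
      stopf("hold_duration > 0 is only meaningful for j_turn bouts")
    }
  }
  if (p$tip_amplitude < 0 || p$tip_amplitude > 1) {
    stopf("tip_amplitude must lie in [0, 1], got %g", p$tip_amplitude)
  }
  if (p$bout_duration <= 0) stopf("bout_duration must be positive")
  if (p$beat_frequency <= 0) stopf("beat_frequency must be positive")
  if (p$noise_sd < 0) stopf("noise_sd must be non-negative")
  structure(p, class = "kinematics_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_tail_trace <- function(points, frame_rate, tail_length_px, base,
                           rest_axis = NULL, flags = NULL) {
  structure(list(points = points, frame_rate = frame_rate,
                 tail_length_px = tail_length_px, base = base,
                 rest_axis = rest_axis,
                 flags = flags %||% rep(FALSE, dim(points)[1])),
            class = "tail_trace")
}

#' @export
print.tail_trace <- function(x, ...) {
  cat(sprintf(
    "<tail_trace> %d frames x %d points, %g f/s, tail length %.1f px\n",
    dim(x$points)[1], dim(x$points)[2], x$frame_rate, x$tail_length_px))
  invisible(x)
}

n_frames <- function(trace) dim(trace$points)[1]

# Tip-deflection time course d(t) (fraction of tail length), per class.
bout_deflection <- function(params, frame_rate) {
  n <- max(1L, round(params$bout_duration / 1000 * frame_rate))
  t <- (seq_len(n) - 1) / frame_rate
  if (params$behavior_class == "j_turn") {
    ramp <- params$ramp_duration / 1000
    hold <- params$hold_duration / 1000
    a <- ifelse(t < ramp, 0.5 * (1 - cos(pi * t / ramp)),
         ifelse(t < ramp + hold, 1,
         ifelse(t < 2 * ramp + hold,
                0.5 * (1 + cos(pi * (t - ramp - hold) / ramp)), 0)))
    sign(params$hold_angle + (params$hold_angle == 0)) *
      params$tip_amplitude * a
  } else {
    f <- params$beat_frequency
    dur <- params$bout_duration / 1000
    t_peak <- 1 / (4 * f)
    # flat envelope to the first quarter-cycle, then mild exponential decay
    # to 95% of the starting amplitude at bout end
    env <- ifelse(t <= t_peak, 1,
                  0.95^((t - t_peak) / max(dur - t_peak, 1e-9)))
    params$tip_amplitude * env * sin(2 * pi * f * t)
  }
}

# Lateral bend profile g(s) along normalized arc position: oscillatory swims
# deflect linearly from the base; j-turns weight the bend toward the tip.
bend_profile <- function(s, behavior_class) {
  if (behavior_class == "j_turn") s^1.5 else s
}

trace_from_deflection <- function(defl, params, frame_rate, tail_points,
                                  geometry) {
  n <- length(defl)
  s <- seq(0, 1, length.out = tail_points)
  g <- bend_profile(s, params$behavior_class)
  axis <- geometry$heading
  perp <- c(axis[2], -axis[1])  # rightward-positive lateral direction
  L <- geometry$length_px
  lateral <- outer(defl, g) * L                       # n x P
  axial <- matrix(s * L, n, tail_points, byrow = TRUE)
  x <- geometry$base[1] + axial * axis[1] + lateral * perp[1]
  y <- geometry$base[2] + axial * axis[2] + lateral * perp[2]
  if (params$noise_sd > 0) {
    x <- x + rnorm(n * tail_points, sd = params$noise_sd * L)
    y <- y + rnorm(n * tail_points, sd = params$noise_sd * L)
  }
  points <- array(c(x, y), dim = c(n, tail_points, 2),
                  dimnames = list(NULL, NULL, c("x", "y")))
  new_tail_trace(points, frame_rate, L, geometry$base, rest_axis = axis)
}

#' Generate one synthetic swim bout
#'
#' Produces a ground-truth tail trace for a single bout. Oscillatory classes
#' (prey-capture forward swims, spontaneous swims) follow a mildly damped
#' sinusoid on the tail-tip deflection with the bend growing linearly from
#' the base; j-turns follow a ramp-hold-release unilateral bend weighted
#' toward the tail tip. Additive Gaussian jitter is applied per point.
#' Deterministic under `seed`.
#'
#' @param params A [kinematics_params()] object.
#' @param frame_rate Frames per second (default 300, the recording rate).
#' @param tail_points Number of midline points per frame (>= 10).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param geometry A [tail_geometry()].
#' @return A `tail_trace`: frames x points x (x, y) array in pixel
#'   coordinates plus frame rate and rest tail length.
#' @export
generate_bout <- function(params, frame_rate = 300, tail_points = 40,
                          seed = NULL, geometry = tail_geometry()) {
  stopifnot(inherits(params, "kinematics_params"))
  if (tail_points < 10) stopf("tail_points must be >= 10")
  if (frame_rate <= 0) stopf("frame_rate must be positive")
  with_seed(seed, {
    defl <- bout_deflection(params, frame_rate)
    trace_from_deflection(defl, params, frame_rate, tail_points, geometry)
  })
}

rest_segment <- function(duration_ms, frame_rate, tail_points, geometry,
                         noise_sd = 0.005) {
  n <- max(0L, round(duration_ms / 1000 * frame_rate))
  p <- kinematics_params("prey_forward", tip_amplitude = 0,
                         noise_sd = noise_sd,
                         bout_duration = max(duration_ms, 1))
  if (n == 0L) {
    tr <- trace_from_deflection(numeric(0), p, frame_rate, tail_points,
                                geometry)
    return(tr)
  }
  trace_from_deflection(rep(0, n), p, frame_rate, tail_points, geometry)
}

concat_traces <- function(traces) {
  points <- do.call(abind_frames, lapply(traces, function(t) t$points))
  tmpl <- traces[[1]]
  new_tail_trace(points, tmpl$frame_rate, tmpl$tail_length_px, tmpl$base,
                 rest_axis = tmpl$rest_axis)
}

abind_frames <- function(...) {
  pieces <- list(...)
  pieces <- pieces[vapply(pieces, function(p) dim(p)[1] > 0, logical(1))]
  dims <- dim(pieces[[1]])
  total <- sum(vapply(pieces, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, dim = c(total, dims[2], dims[3]),
               dimnames = list(NULL, NULL, c("x", "y")))
  at <- 1L
  for (p in pieces) {
    k <- dim(p)[1]
    out[at:(at + k - 1L), , ] <- p
    at <- at + k
  }
  out
}

#' Generate a synthetic trial (rest and bout segments interleaved)
#'
#' Concatenates rest segments (straight tail plus coordinate jitter) with
#' bouts generated from `class_sequence`, recording the ground-truth frame
#' interval and class of every bout. Bout intervals are half-open
#' `[start_frame, end_frame)`, 1-based.
#'
#' @param class_sequence List of [kinematics_params()], one per bout (may be
#'   empty for an all-rest trial, provided rest segments are given).
#' @param rest_durations Rest durations in ms: either length
#'   `length(class_sequence) + 1` (rest before, between, after) or a single
#'   value recycled.
#' @param frame_rate Frames per second.
#' @param tail_points Midline points per frame.
#' @param seed Integer seed (bit-reproducible trials).
#' @param geometry A [tail_geometry()].
#' @param rest_noise_sd Rest-segment coordinate jitter (fraction of tail
#'   length).
#' @return A `synthetic_trial`: list with `trace`, `bout_truth`
#'   (data.frame `start_frame`, `end_frame`, `class`), `frame_rate`, `seed`.
#' @export
generate_trial <- function(class_sequence, rest_durations = 200,
                           frame_rate = 300, tail_points = 40, seed = NULL,
                           geometry = tail_geometry(), rest_noise_sd = 0.005) {
  n_bouts <- length(class_sequence)
  if (length(rest_durations) == 1L) {
    rest_durations <- rep(rest_durations, n_bouts + 1L)
  }
  if (length(rest_durations) != n_bouts + 1L) {
    stopf("need %d rest durations for %d bouts (got %d)",
          n_bouts + 1L, n_bouts, length(rest_durations))
  }
  if (n_bouts == 0L && all(rest_durations <= 0)) {
    stopf("empty trial: no bouts and no rest segments")
  }
  with_seed(seed, {
    segments <- list()
    truth <- data.frame(start_frame = integer(0), end_frame = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
    at <- 1L
    for (i in seq_len(n_bouts + 1L)) {
      r <- rest_segment(rest_durations[i], frame_rate, tail_points, geometry,
                        noise_sd = rest_noise_sd)
      segments <- c(segments, list(r))
      at <- at + n_frames(r)
      if (i <= n_bouts) {
        b <- generate_bout(class_sequence[[i]], frame_rate, tail_points,
                           seed = NULL, geometry = geometry)
        segments <- c(segments, list(b))
        truth <- rbind(truth, data.frame(
          start_frame = at, end_frame = at + n_frames(b),
          class = class_sequence[[i]]$behavior_class,
          stringsAsFactors = FALSE))
        at <- at + n_frames(b)
      }
    }
    structure(list(trace = concat_traces(segments), bout_truth = truth,
                   frame_rate = frame_rate, seed = seed),
              class = "synthetic_trial")
  })
}

#' Sample per-bout kinematic parameters around the class defaults
#'
#' Draws `n` parameter sets for a behavior class with biological variability:
#' multiplicative amplitude/duration/frequency jitter (truncated Gaussian,
#' mean 1) and, for j-turns, a uniform hold duration and a random turn side.
#' Jitter defaults are deliberately tight so the class-defining statistics of
#' the defaults (17% / 48% amplitude, 27 ms bend mode) remain the population
#' ground truth.
#'
#' @param behavior_class Class name.
#' @param n Number of bouts.
#' @param seed Integer seed.
#' @param amplitude_cv,duration_cv,frequency_cv Coefficients of variation of
#'   the multiplicative jitters (truncated at +/- 3 cv).
#' @param hold_range j-turn hold duration range in ms (uniform).
#' @param hold_angle_sd j-turn hold-angle jitter in degrees.
#' @return List of [kinematics_params()].
#' @export
sample_bout_params <- function(behavior_class, n, seed = NULL,
                               amplitude_cv = 0.05, duration_cv = 0.10,
                               frequency_cv = 0.05,
                               hold_range = c(100, 600), hold_angle_sd = 3) {
  with_seed(seed, {
    jitter <- function(cv, k) {
      z <- rnorm(k)
      1 + cv * pmax(pmin(z, 3), -3)
    }
    base <- kinematics_params(behavior_class)
    amp <- base$tip_amplitude * jitter(amplitude_cv, n)
    dur <- base$bout_duration * jitter(duration_cv, n)
    freq <- base$beat_frequency * jitter(frequency_cv, n)
    if (behavior_class == "j_turn") {
      holds <- runif(n, hold_range[1], hold_range[2])
      angles <- (base$hold_angle + rnorm(n, sd = hold_angle_sd)) *
        sample(c(-1, 1), n, replace = TRUE)
      lapply(seq_len(n), function(i) {
        kinematics_params("j_turn", hold_duration = holds[i],
                          hold_angle = angles[i])
      })
    } else {
      lapply(seq_len(n), function(i) {
        kinematics_params(behavior_class, tip_amplitude = min(amp[i], 1),
                          beat_frequency = freq[i], bout_duration = dur[i])
      })
    }
  })
}

#' Render a tail trace as synthetic high-speed video
#'
#' Draws the tail midline of every frame as a bright stroke with a Gaussian
#' cross-section (`tail_width_px` = full width at half maximum) over a dark,
#' noisy background, emulating the IR-illuminated recordings (default
#' 300 x 300 px geometry). The ground-truth trace is stored alongside the
#' frames.
#'
#' @param trace A `tail_trace`.
#' @param tail_width_px Stroke FWHM in pixels.
#' @param contrast Peak stroke intensity above background.
#' @param background Background intensity level.
#' @param background_noise_sd Gaussian noise sd (intensity units).
#' @param dims Frame size `c(height, width)`.
#' @param seed Integer seed for the background noise.
#' @return A `rendered_video`: list with `frames` (height x width x frames
#'   array, intensities clamped to `[0, 255]`), `ground_truth`, and the
#'   rendering parameters.
#' @export
render_video <- function(trace, tail_width_px = 4, contrast = 200,
                         background = 10, background_noise_sd = 5,
                         dims = c(300, 300), seed = NULL) {
  stopifnot(inherits(trace, "tail_trace"))
  pts <- trace$points
  n <- dim(pts)[1]
  margin <- 1
  bad <- which(apply(pts, 1, function(m) {
    any(m[, 1] < margin | m[, 1] > dims[2] - 1 - margin |
        m[, 2] < margin | m[, 2] > dims[1] - 1 - margin)
  }))
  if (length(bad)) {
    stopf("tail points out of frame at frame %d (of %d flagged)",
          bad[1], length(bad))
  }
  dense <- lapply(seq_len(n), function(i) {
    m <- pts[i, , ]
    k <- max(2L, ceiling(arc_length(m) / 0.75))
    resample_polyline(m, k)
  })
  sigma <- tail_width_px / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  frames <- with_seed(seed, {
    cpp_render_frames(dense, dims[1], dims[2], sigma, contrast, background,
                      background_noise_sd)
  })
  structure(list(frames = frames, ground_truth = trace,
                 tail_width_px = tail_width_px, contrast = contrast,
                 background = background,
                 background_noise_sd = background_noise_sd),
            class = "rendered_video")
}

#' Circular ROI mask
#'
#' @param dims Image size `c(height, width)`.
#' @param center `c(x, y)` 0-based pixel center.
#' @param radius Radius in pixels.
#' @return Logical height x width matrix.
#' @export
disk_mask <- function(dims, center, radius) {
  x <- matrix(seq_len(dims[2]) - 1, dims[1], dims[2], byrow = TRUE)
  y <- matrix(seq_len(dims[1]) - 1, dims[1], dims[2])
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Default two-ROI layout for synthetic fluorescence movies
#'
#' A "prey_tuned" ROI (emulating the pretectal arborization field that
#' responds maximally to 2-3 degree dots) and a "large_stimulus" ROI
#' (emulating the neighbouring field that responds only to larger stimuli).
#'
#' @param dims Image size, default 128 x 128 as in the confocal recordings.
#' @return Named list of logical masks.
#' @export
default_roi_layout <- function(dims = c(128, 128)) {
  list(prey_tuned = disk_mask(dims, c(40, 64), 6),
       large_stimulus = disk_mask(dims, c(88, 64), 6))
}

#' Stimulus tuning of the synthetic ROI types
#'
#' Response gain in `[0, 1]` as a function of dot size (degrees of visual
#' field) and speed (degrees/s). `prey_tuned` peaks at 2.5 degrees and
#' 90 degrees/s and responds weakly above 6 degrees; `large_stimulus` rises
#' sigmoidally above about 8 degrees.
#'
#' @param roi_type `"prey_tuned"` or `"large_stimulus"`.
#' @param size_deg Dot diameter in degrees.
#' @param speed_deg_s Dot speed in degrees/s.
#' @return Numeric gain(s) in `[0, 1]`.
#' @export
stimulus_tuning <- function(roi_type = c("prey_tuned", "large_stimulus"),
                            size_deg, speed_deg_s = 90) {
  roi_type <- match.arg(roi_type)
  if (roi_type == "prey_tuned") {
    size_gain <- exp(-(log2(size_deg / 2.5))^2 / (2 * 0.55^2))
    speed_gain <- exp(-(log2(speed_deg_s / 90))^2 / (2 * 1.1^2))
    size_gain * speed_gain
  } else {
    1 / (1 + exp(-(size_deg - 8) / 1.5))
  }
}

#' GCaMP-like calcium response time course
#'
#' Difference-of-exponentials kernel placed at a stimulus onset; peak scaled
#' to `amplitude` (units of ΔF/F).
#'
#' @param n_frames Length of the time course.
#' @param onset Onset frame (1-based).
#' @param amplitude Peak ΔF/F.
#' @param frame_rate Acquisition rate in Hz (default 3.4, the confocal rate).
#' @param rise,decay Rise and decay time constants in seconds.
#' @return Numeric vector of length `n_frames`.
#' @export
calcium_response <- function(n_frames, onset, amplitude, frame_rate = 3.4,
                             rise = 0.3, decay = 2.5) {
  t <- (seq_len(n_frames) - onset) / frame_rate
  k <- ifelse(t < 0, 0, exp(-t / decay) - exp(-t / rise))
  pk <- max(k)
  if (pk <= 0) return(rep(0, n_frames))
  amplitude * k / pk
}

#' Generate a synthetic fluorescence movie with ROI-localized responses
#'
#' Pixels inside each ROI follow `baseline_level * (1 + dff(t))` for that
#' ROI's ΔF/F time course; all other pixels sit at `baseline_level`.
#' Additive Gaussian noise everywhere. Emulates registered confocal movies
#' (default 128 x 128 px); shot noise is not modelled.
#'
#' @param roi_layout Named list of disjoint logical masks (height x width).
#' @param response_spec Named list (same names) of numeric ΔF/F time courses
#'   of length `n_frames`.
#' @param n_frames Number of frames (> 25 so a percentile baseline window
#'   fits).
#' @param baseline_level Baseline fluorescence intensity.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param frame_rate Acquisition rate in Hz.
#' @param seed Integer seed.
#' @return A `fluorescence_movie`: list with `frames` (height x width x
#'   frames), `roi_truth` (masks + time courses), `baseline_level`,
#'   `noise_sd`, `frame_rate`.
#' @export
generate_fluorescence_movie <- function(roi_layout, response_spec, n_frames,
                                        baseline_level = 100, noise_sd = 2,
                                        frame_rate = 3.4, seed = NULL) {
  if (n_frames <= 25) stopf("n_frames must exceed 25")
  if (is.null(names(roi_layout)) || any(names(roi_layout) == "")) {
    stopf("roi_layout must be a named list of masks")
  }
  if (!setequal(names(roi_layout), names(response_spec))) {
    stopf("response_spec names must match roi_layout names")
  }
  masks <- lapply(roi_layout, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  total <- Reduce(`+`, masks)
  if (any(total > 1)) stopf("ROI masks overlap; masks must be disjoint")
  dims <- dim(masks[[1]])
  frames <- array(baseline_level, dim = c(dims[1], dims[2], n_frames))
  for (nm in names(masks)) {
    dff <- response_spec[[nm]]
    if (length(dff) != n_frames) {
      stopf("response for ROI '%s' has length %d, expected %d",
            nm, length(dff), n_frames)
    }
    idx <- which(masks[[nm]])
    for (t in seq_len(n_frames)) {
      frames[idx + (t - 1L) * prod(dims)] <-
        baseline_level * (1 + dff[t])
    }
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      frames <- frames + rnorm(length(frames), sd = noise_sd)
    }
  })
  structure(list(frames = frames,
                 roi_truth = list(masks = masks, dff = response_spec),
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 frame_rate = frame_rate),
            class = "fluorescence_movie")
}
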