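test_that("generators are bit-reproducible under a fixed seed", {
  p <- kinematics_params("spontaneous")
  expect_identical(generate_bout(p, seed = 42), generate_bout(p, seed = 42))
  tr1 <- generate_trial(list(p), seed = 7)
  tr2 <- generate_trial(list(p), seed = 7)
  expect_identical(tr1, tr2)
  v1 <- render_video(tr1$trace, seed = 3)
  v2 <- render_video(tr2$trace, seed = 3)
  expect_identical(v1$frames, v2$frames)
  lay <- default_roi_layout(c(32, 32))
  lay <- lapply(lay, function(m) m[1:32, 1:32])
  resp <- list(prey_tuned = rep(0, 30), large_stimulus = rep(0, 30))
  expect_identical(
    generate_fluorescence_movie(lay, resp, 30, seed = 9)$frames,
    generate_fluorescence_movie(lay, resp, 30, seed = 9)$frames)
})

test_that("zero amplitude and zero noise give a straight tail", {
  p <- kinematics_params("prey_forward", tip_amplitude = 0, noise_sd = 0)
  tr <- generate_bout(p, seed = 1)
  expect_equal(diff(range(tr$points[, , 1])), 0)
})

test_that("peak tip deflection matches tip_amplitude for noise-free bouts", {
  for (class in c("prey_forward", "spontaneous")) {
    p <- kinematics_params(class, noise_sd = 0)
    tr <- generate_bout(p, seed = 1)
    peak_defl <- max(abs(tr$points[, 40, 1] - tr$base[1])) /
      tr$tail_length_px
    expect_equal(peak_defl, p$tip_amplitude, tolerance = 0.01)
  }
})

test_that("a j-turn holds its bend beyond 20 degrees for the hold duration", {
  p <- kinematics_params("j_turn", hold_duration = 300)
  tr <- generate_bout(p, seed = 5)
  ks <- compute_kinematics(tr, rest_axis = c(0, 1))
  dur <- longest_bend_duration(ks, c(1L, length(ks$tail_angle) + 1L))
  expect_gte(dur, 300)
})

test_that("invalid kinematic parameters are rejected", {
  expect_error(kinematics_params("prey_forward", tip_amplitude = -0.1),
               "tip_amplitude")
  expect_error(kinematics_params("prey_forward", bout_duration = 0),
               "bout_duration")
  expect_error(kinematics_params("prey_forward", beat_frequency = -1),
               "beat_frequency")
  expect_error(kinematics_params("prey_forward", hold_duration = 100),
               "j_turn")
  expect_error(generate_bout(kinematics_params("spontaneous"),
                             tail_points = 5), "tail_points")
})

test_that("trial assembly records ground-truth bout intervals exactly", {
  durations <- c(150, 200, 300)
  params <- lapply(durations, function(d) {
    kinematics_params("prey_forward", bout_duration = d)
  })
  trial <- generate_trial(params, rest_durations = 100, seed = 2)
  expect_equal(nrow(trial$bout_truth), 3)
  # frame counts equal duration x rate, rounded (hand count at 300 f/s)
  expect_equal(trial$bout_truth$end_frame - trial$bout_truth$start_frame,
               round(durations * 300 / 1000))
  expect_true(all(diff(c(t(trial$bout_truth[, 1:2]))) >= 0))  # ordered
  expect_lte(max(trial$bout_truth$end_frame),
             dim(trial$trace$points)[1] + 1)
  # zero bouts -> all-rest trace and empty truth
  rest_only <- generate_trial(list(), rest_durations = 500, seed = 3)
  expect_equal(nrow(rest_only$bout_truth), 0)
  expect_equal(dim(rest_only$trace$points)[1], 150)
  expect_error(generate_trial(list(), rest_durations = 0), "empty trial")
})

test_that("prey-capture swims have lower tail-beat amplitude than spontaneous", {
  amp <- function(class, n) {
    ps <- sample_bout_params(class, n, seed = 10)
    mean(vapply(seq_along(ps), function(i) {
      tr <- generate_bout(ps[[i]], seed = 100 + i)
      ks <- compute_kinematics(tr, rest_axis = c(0, 1))
      bout_amplitude(ks, c(1L, length(ks$tail_angle) + 1L))
    }, numeric(1)))
  }
  expect_lt(amp("prey_forward", 20), amp("spontaneous", 20))
})

test_that("rendering draws the tail where the ground truth says it is", {
  # noiseless straight vertical tail: every row's argmax sits on the tail x
  tr <- static_trace(straight_polyline(), n_frames = 2)
  vid <- render_video(tr, background_noise_sd = 0, seed = 1)
  frame <- vid$frames[, , 1]
  rows <- 61:219  # rows covered by the tail (y = 60..220)
  ridge_x <- apply(frame[rows + 1, ], 1, which.max) - 1
  expect_true(all(ridge_x == 150))
  # a bent, noise-free bout re-extracted by per-row argmax: within width/2
  p <- kinematics_params("prey_forward", noise_sd = 0)
  bout <- generate_bout(p, seed = 4)
  vid2 <- render_video(bout, background_noise_sd = 0, seed = 1)
  f10 <- vid2$frames[, , 10]
  truth <- bout$points[10, , ]
  for (k in c(10, 25, 40)) {
    row <- round(truth[k, 2])
    ridge <- which.max(f10[row + 1, ]) - 1
    expect_lte(abs(ridge - truth[k, 1]), vid2$tail_width_px / 2)
  }
})

test_that("rendering rejects traces that leave the frame", {
  poly <- straight_polyline(base = c(295, 60))
  tr <- static_trace(poly, n_frames = 2)
  tr$points[2, 40, 1] <- 320
  expect_error(render_video(tr), "frame 2")
})

test_that("fluorescence movies put responses only inside their ROI", {
  lay <- default_roi_layout()
  n <- 60
  resp <- list(prey_tuned = rep(0, n), large_stimulus = rep(0, n))
  quiet <- generate_fluorescence_movie(lay, resp, n, baseline_level = 100,
                                       noise_sd = 1, seed = 2)
  expect_equal(mean(quiet$frames), 100, tolerance = 0.01)
  # boxcar response on a single-pixel ROI recovers its Delta F/F closed form
  mask <- matrix(FALSE, 128, 128)
  mask[64, 64] <- TRUE
  dff_true <- c(rep(0, 30), rep(1, 10), rep(0, 20))
  mov <- generate_fluorescence_movie(list(roi = mask), list(roi = dff_true),
                                     n, noise_sd = 0, seed = 1)
  expect_equal(mov$frames[64, 64, 35], 200)
  expect_equal(mov$frames[64, 64, 10], 100)
  # overlapping masks are an invalid layout
  expect_error(
    generate_fluorescence_movie(list(a = mask, b = mask),
                                list(a = dff_true, b = dff_true), n),
    "overlap")
})

test_that("the prey-tuned ROI type peaks at 2-3 degree dots", {
  sizes <- c(0.5, 1, 2, 2.5, 3, 6, 10, 14)
  g <- stimulus_tuning("prey_tuned", sizes)
  expect_equal(sizes[which.max(g)], 2.5)
  expect_true(all(g[sizes >= 6] < 0.3 * max(g)))
  big <- stimulus_tuning("large_stimulus", sizes)
  expect_lt(big[1], 0.05)
  expect_gt(big[length(sizes)], 0.9)
})
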