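test_that("sliding percentile baseline follows the rank-interpolation convention", {
  # constant pixel
  expect_equal(sliding_percentile_baseline(rep(100, 60)), rep(100, 60))
  # a full 1..25 window reproduces the type-7 quantile, frozen from the
  # sort-and-rank oracle: h = 24 * 0.08 + 1 = 2.92 -> 2.92
  tr <- c(1:25, rep(100, 10))
  expect_equal(sliding_percentile_baseline(tr, 25, 8)[13], 2.92)
  # exact agreement with a brute-force sort + rank oracle on random traces
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(80, 100, 10)
    got <- sliding_percentile_baseline(x, 25, 8)
    want <- vapply(seq_along(x), function(t) {
      quantile(x[max(1, t - 12):min(80, t + 12)], 0.08, type = 7,
               names = FALSE)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(sliding_percentile_baseline(rnorm(20), 25), "invalid window")
})

test_that("raising a raw value never lowers any baseline value", {
  set.seed(5)
  x <- rnorm(60)
  b0 <- sliding_percentile_baseline(x, 25, 8)
  for (i in c(1, 17, 30, 60)) {
    x2 <- x
    x2[i] <- x2[i] + 3
    expect_true(all(sliding_percentile_baseline(x2, 25, 8) >= b0 - 1e-12))
  }
})

test_that("Delta F/F is exact arithmetic on the baseline", {
  mov <- array(100, dim = c(4, 4, 40))
  base <- array(100, dim = c(4, 4, 40))
  d0 <- compute_dff(mov, base)
  expect_true(all(d0$values == 0))
  # boxcar doubling of the baseline -> Delta F/F = 1 during the boxcar
  mov[2, 2, 10:15] <- 200
  d1 <- compute_dff(mov, base)
  expect_equal(d1$values[2, 2, 12], 1)
  expect_equal(d1$values[2, 2, 30], 0)
  # reconstruction raw = baseline * (1 + dff) is exact on unmasked pixels
  set.seed(6)
  mov2 <- array(rnorm(4 * 4 * 40, 100, 5), dim = c(4, 4, 40))
  base2 <- sliding_percentile_baseline(mov2)
  d2 <- compute_dff(mov2, base2)
  expect_equal(base2 * (1 + d2$values), mov2, tolerance = 1e-12)
  # nonpositive baselines mask the pixel with a warning
  base3 <- base
  base3[1, 1, 5] <- 0
  expect_warning(d3 <- compute_dff(mov, base3), "masked")
  expect_true(all(is.na(d3$values[1, 1, ])))
  expect_false(anyNA(d3$values[2, 2, ]))
  expect_error(compute_dff(mov, base[, , 1:10]), "shapes differ")
})

test_that("condition ratio maps divide the per-pixel max projections", {
  set.seed(7)
  pre <- array(abs(rnorm(8 * 8 * 30, 0.2, 0.02)), dim = c(8, 8, 30))
  expect_equal(condition_ratio_map(pre, pre),
               matrix(1, 8, 8))
  # an ROI responding only post shows the truth ratio
  post <- pre
  post[3, 3, 10] <- 0.8
  r <- condition_ratio_map(pre, post)
  expect_equal(r[3, 3], 0.8 / max(pre[3, 3, ]), tolerance = 1e-12)
  # swap-and-invert symmetry on unmasked pixels
  r_swapped <- condition_ratio_map(post, pre, floor = 0)
  expect_equal(r[3, 3], 1 / r_swapped[3, 3], tolerance = 1e-12)
  # quiet pre-segment pixels are masked rather than divided by noise
  quiet_pre <- array(0.01, dim = c(8, 8, 30))
  expect_true(all(is.na(condition_ratio_map(quiet_pre, post))))
  expect_error(condition_ratio_map(pre, post[1:4, , ]), "shapes differ")
})

test_that("ROI responses are spatial means with their peak recorded", {
  vals <- array(0, dim = c(8, 8, 20))
  mask <- matrix(FALSE, 8, 8)
  mask[2, 5] <- TRUE
  vals[2, 5, ] <- sin(seq(0, pi, length.out = 20))
  r <- roi_response(vals, mask, condition = "3")
  expect_equal(r$timecourse, vals[2, 5, ])
  expect_equal(r$peak, max(vals[2, 5, ]))
  zero <- roi_response(array(0, dim = c(8, 8, 20)), mask)
  expect_equal(zero$timecourse, rep(0, 20))
  expect_error(roi_response(vals, matrix(FALSE, 8, 8)), "empty ROI")
})

test_that("recovered ROI peaks track the generator truth", {
  lay <- default_roi_layout()
  amp <- 0.8
  n <- 60
  resp <- list(prey_tuned = c(rep(0, 20), rep(amp, 8), rep(0, 32)),
               large_stimulus = rep(0, n))
  peaks <- vapply(1:30, function(i) {
    mov <- generate_fluorescence_movie(lay, resp, n, noise_sd = 0.5,
                                       seed = 100 + i)
    roi_response(compute_dff(mov$frames), lay$prey_tuned)$peak
  }, numeric(1))
  # the percentile baseline sits ~1.4 sd below the mean under Gaussian
  # noise, inflating Delta F/F by about (1 + amp) * 1.4 sigma / F0
  bias_bound <- (1 + amp) * 2 * 1.4 * 0.5 / 100
  expect_lt(abs(mean(peaks) - amp), bias_bound + 2 * sd(peaks) / sqrt(30))
})

test_that("response tuning normalizes to each larva's maximum", {
  df <- data.frame(larva = rep(c("a", "b"), each = 3),
                   condition = rep(c("1", "2.5", "10"), 2),
                   response = c(0.2, 0.8, 0.1, 0.1, 0.4, 0.05))
  tun <- response_tuning(df)
  expect_equal(tun$mean[tun$condition == "2.5"], 100)
  expect_equal(tun$sem, c(0, 0, 0))
  # synthetic prey-tuned ROI: maximal at 2-3 degrees, much weaker above 6
  sizes <- c(1, 2.5, 6, 10)
  lay <- default_roi_layout()
  responses <- do.call(rbind, lapply(1:3, function(larva) {
    do.call(rbind, lapply(seq_along(sizes), function(k) {
      amp <- 0.9 * stimulus_tuning("prey_tuned", sizes[k])
      resp <- list(prey_tuned = calcium_response(40, 15, amp),
                   large_stimulus = rep(0, 40))
      mov <- generate_fluorescence_movie(lay, resp, 40, noise_sd = 0.5,
                                         seed = 10 * larva + k)
      data.frame(larva = larva, condition = sizes[k],
                 response = roi_response(compute_dff(mov$frames),
                                         lay$prey_tuned)$peak)
    }))
  }))
  tun2 <- response_tuning(responses)
  expect_equal(tun2$condition[which.max(tun2$mean)], "2.5")
  expect_lt(tun2$mean[tun2$condition == "10"],
            0.4 * tun2$mean[tun2$condition == "2.5"])
})

test_that("the normality gate picks the paper's two-group tests", {
  # exact rank-sum p on tiny samples: 2 of the 20 label assignments are as
  # extreme as the observed split
  cg <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "wilcoxon")
  expect_equal(cg$p_value, 0.1)
  expect_identical(cg$test, "Wilcoxon rank sum")
  # identical samples cannot be distinguished
  same <- compare_groups(c(1, 1, 2, 8), c(1, 1, 2, 8), test = "wilcoxon")
  expect_equal(same$p_value, 1)
  auto_same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(auto_same$p_value, 1)
  # gate: heavy-tailed data go to the rank sum, Gaussian data to the t-test
  set.seed(8)
  skewed <- compare_groups(rexp(40)^3, rexp(40)^3)
  expect_identical(skewed$test, "Wilcoxon rank sum")
  normal <- compare_groups(rnorm(40), rnorm(40, 0.5))
  expect_identical(normal$test, "t-test")
  expect_true(is.finite(normal$levene$p_value))
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient")
})

test_that("jarque_bera_test matches its closed form", {
  x <- c(2, 4, 4, 7, 8, 9, 12)
  n <- length(x)
  m <- mean(x)
  s <- mean((x - m)^3) / mean((x - m)^2)^1.5
  k <- mean((x - m)^4) / mean((x - m)^2)^2
  jb <- jarque_bera_test(x)
  expect_equal(jb$statistic, n * (s^2 / 6 + (k - 3)^2 / 24))
  expect_equal(jb$p_value, pchisq(jb$statistic, 2, lower.tail = FALSE))
})

test_that("translation drift beyond tolerance is reported", {
  set.seed(9)
  ref <- matrix(rnorm(64 * 64), 64, 64)
  ref[20:30, 20:30] <- 10
  mov <- array(0, dim = c(64, 64, 2))
  mov[, , 1] <- ref
  mov[, , 2] <- ref[c(61:64, 1:60), ]  # shifted by 4 rows
  expect_warning(d <- detect_translation_drift(mov), "drift")
  expect_equal(abs(d$dy[2]), 4)
  mov[, , 2] <- ref
  expect_silent(detect_translation_drift(mov))
})
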