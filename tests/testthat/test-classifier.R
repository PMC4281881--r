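two_cloud_set <- function(n = 40, gap = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  f1 <- c(rnorm(n, 0, sd), rnorm(n, gap, sd))
  labeled_bout_set(blank_features(2 * n, f1_max_tail_curvature = f1),
                   rep(c("prey_capture", "spontaneous"), each = n))
}

test_that("stratified folds balance class counts and are content-keyed", {
  d <- two_cloud_set(37)
  folds <- make_stratified_folds(d, 5)
  for (cl in levels(d$labels)) {
    sizes <- tabulate(folds[d$labels == cl], 5)
    expect_lte(diff(range(sizes)), 1)
  }
  # permuting rows permutes the assignment identically (content-keyed)
  perm <- sample(seq_along(d$labels))
  dp <- labeled_bout_set(d$features[perm, ], d$labels[perm])
  expect_identical(make_stratified_folds(dp, 5), folds[perm])
  tiny <- labeled_bout_set(blank_features(6, f1_max_tail_curvature = 1:6),
                           c(rep("prey_capture", 3), rep("spontaneous", 3)))
  expect_error(cross_validate(tiny, folds = 5), "stratification")
})

test_that("linearly separable clouds cross-validate perfectly", {
  cv <- cross_validate(two_cloud_set(), feature_subset =
                         "f1_max_tail_curvature")
  expect_equal(cv$pooled_accuracy, 1.0)
  expect_equal(sum(cv$confusion), 80)
  # permuting training order leaves the pooled accuracy unchanged
  d <- two_cloud_set(53, gap = 2, sd = 1, seed = 5)
  perm <- sample(seq_along(d$labels))
  dp <- labeled_bout_set(d$features[perm, ], d$labels[perm])
  expect_equal(cross_validate(dp)$pooled_accuracy,
               cross_validate(d)$pooled_accuracy)
})

test_that("overlapping Gaussians cross-validate near the Bayes rate", {
  set.seed(7)
  n <- 500
  f1 <- c(rnorm(n, -1), rnorm(n, 1))
  d <- labeled_bout_set(blank_features(2 * n, f1_max_tail_curvature = f1),
                        rep(c("prey_capture", "spontaneous"), each = n))
  cv <- cross_validate(d, feature_subset = "f1_max_tail_curvature")
  expect_equal(cv$pooled_accuracy, pnorm(1), tolerance = 0.03 / pnorm(1))
})

test_that("label-flip symmetry swaps the confusion quadrants", {
  d <- two_cloud_set(50, gap = 2, sd = 1, seed = 9)
  flipped <- labeled_bout_set(
    d$features, ifelse(d$labels == "prey_capture", "spontaneous",
                       "prey_capture"))
  c1 <- cross_validate(d)$confusion
  c2 <- cross_validate(flipped)$confusion
  expect_equal(unname(c1), unname(c2[2:1, 2:1]))
})

test_that("parameter selection prefers the smallest sufficient subset", {
  set.seed(11)
  n <- 80
  feats <- blank_features(2 * n,
    f1_max_tail_curvature = c(rnorm(n, -3), rnorm(n, 3)),
    f2_n_peaks_tail_angle = rnorm(2 * n),
    f3_mean_tip_angle = rnorm(2 * n),
    f4_max_tail_angle = rnorm(2 * n),
    f5_mean_tip_position = rnorm(2 * n))
  d <- labeled_bout_set(feats, rep(c("prey_capture", "spontaneous"),
                                   each = n))
  sel <- select_parameters(d, candidate_order = feature_names()[1:5])
  expect_equal(sel$selected_k, 1)
  # all-tie accuracies break toward minimality
  dup <- blank_features(2 * n,
    f1_max_tail_curvature = feats$f1_max_tail_curvature,
    f2_n_peaks_tail_angle = feats$f1_max_tail_curvature,
    f3_mean_tip_angle = feats$f1_max_tail_curvature)
  dtie <- labeled_bout_set(dup, d$labels)
  stie <- select_parameters(dtie, candidate_order = feature_names()[1:3])
  expect_equal(stie$selected_k, 1)
  expect_error(select_parameters(d, candidate_order = "f1_max_tail_curvature"),
               "2 candidates")
})

test_that("training is reproducible and stores its own in-sample behavior", {
  d <- two_cloud_set(30, gap = 3, sd = 1, seed = 13)
  clf1 <- train_bout_classifier(d, feature_subset = "f1_max_tail_curvature")
  clf2 <- train_bout_classifier(d, feature_subset = "f1_max_tail_curvature")
  p1 <- classify_bouts(clf1, d$features)
  expect_identical(p1, classify_bouts(clf2, d$features))
  expect_identical(p1, clf1$training_predictions)
  expect_equal(mean(p1 == d$labels), clf1$training_accuracy)
  # one distinct bout per class classifies itself correctly
  tiny <- labeled_bout_set(
    blank_features(2, f1_max_tail_curvature = c(0, 10)),
    c("prey_capture", "spontaneous"))
  ctiny <- train_bout_classifier(tiny,
                                 feature_subset = "f1_max_tail_curvature")
  expect_identical(as.character(classify_bouts(ctiny, tiny$features)),
                   c("prey_capture", "spontaneous"))
})

test_that("degenerate features are dropped and schemas are enforced", {
  d <- two_cloud_set(20)
  expect_warning(
    clf <- train_bout_classifier(
      d, feature_subset = c("f1_max_tail_curvature", "f3_mean_tip_angle")),
    "zero-variance")
  expect_identical(clf$feature_subset, "f1_max_tail_curvature")
  expect_length(classify_bouts(clf, d$features[0, ]), 0)
  expect_error(classify_bouts(clf, data.frame(x = 1)), "schema")
  one_class <- labeled_bout_set(blank_features(4),
                                rep("prey_capture", 4))
  expect_error(train_bout_classifier(one_class), "both classes")
})

test_that("missing f6 is imputed with the training median before classification", {
  set.seed(15)
  n <- 30
  feats <- blank_features(2 * n,
    f1_max_tail_curvature = c(rnorm(n, 0), rnorm(n, 6)),
    f6_mean_frames_between_peaks = c(rnorm(2 * n - 3, 10), rep(NA, 3)))
  d <- labeled_bout_set(feats, rep(c("prey_capture", "spontaneous"),
                                   each = n))
  clf <- train_bout_classifier(
    d, feature_subset = c("f1_max_tail_curvature",
                          "f6_mean_frames_between_peaks"))
  expect_false(anyNA(classify_bouts(clf, d$features)))
})

test_that("prey capture scores are trial-time percentages", {
  bouts <- data.frame(start_frame = c(10, 200), end_frame = c(85, 250),
                      label = c("prey_capture", "spontaneous"))
  expect_equal(prey_capture_score(bouts, 300), 25)
  expect_equal(prey_capture_score(bouts[0, ], 300), 0)
  # additive over disjoint bout sets, bounded by 100
  more <- rbind(bouts,
                data.frame(start_frame = 100, end_frame = 130,
                           label = "prey_capture"))
  expect_equal(prey_capture_score(more, 300),
               prey_capture_score(bouts, 300) +
                 prey_capture_score(more[3, ], 300))
  full <- data.frame(start_frame = 1, end_frame = 301,
                     label = "prey_capture")
  expect_equal(prey_capture_score(full, 300), 100)
  expect_error(prey_capture_score(bouts, 0), "positive")
  expect_error(prey_capture_score(bouts, 100), "outside")
})

test_that("tuning curves normalize per larva before averaging", {
  one <- data.frame(larva = "a", condition = c("1", "3", "10"),
                    score = c(10, 40, 20))
  tc <- tuning_curve(one)
  expect_equal(tc$mean[tc$condition == "3"], 100)
  # proportional larvae give identical normalized curves (scale invariance)
  two <- rbind(one, transform(one, larva = "b", score = score * 7))
  tc2 <- tuning_curve(two)
  expect_equal(tc2$mean, tc$mean)
  expect_equal(tc2$sem, c(0, 0, 0))
  # all-zero larvae are excluded with a warning
  three <- rbind(two, data.frame(larva = "c", condition = c("1", "3", "10"),
                                 score = 0))
  expect_warning(tc3 <- tuning_curve(three), "no positive")
  expect_equal(tc3$mean, tc$mean)
})

test_that("low responders to the reference stimulus are excluded", {
  df <- data.frame(larva = rep(c("a", "b"), each = 2),
                   condition = rep(c("3", "10"), 2),
                   score = c(50, 20, 10, 60))
  kept <- exclude_low_responders(df, "3")
  expect_identical(unique(kept$larva), "a")
})
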