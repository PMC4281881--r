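#' Stratified fold assignment balancing class proportions and feature means
#'
#' Splits the bouts into `folds` groups of approximately equal mean: within
#' each class, bouts are ordered by the first feature (ties broken by the
#' remaining features) and dealt to folds in a serpentine pattern, which
#' equalizes class counts (sizes differ by at most one per class) and
#' approximately equalizes the per-fold feature means. Keyed on content, not
#' row order, so permuting the data does not change the assignment.
#'
#' @param data A [labeled_bout_set()].
#' @param folds Number of folds.
#' @param feature_subset Features used for the balancing order (first one
#'   drives the serpentine).
#' @return Integer vector of fold ids (1..folds), one per bout.
#' @export
make_stratified_folds <- function(data, folds = 5,
                                  feature_subset = feature_names()) {
  stopifnot(inherits(data, "labeled_bout_set"))
  counts <- tabulate(data$labels, nbins = nlevels(data$labels))
  if (any(counts < folds)) {
    stopf("stratification error: a class has fewer members (%d) than folds",
          min(counts))
  }
  X <- data$features[feature_subset]
  X[is.na(X)] <- 0
  assignment <- integer(nrow(X))
  serpentine <- c(seq_len(folds), rev(seq_len(folds)))
  for (cl in levels(data$labels)) {
    rows <- which(data$labels == cl)
    ord <- do.call(order, as.list(X[rows, , drop = FALSE]))
    pattern <- rep_len(serpentine, length(rows))
    assignment[rows[ord]] <- pattern
  }
  assignment
}

svm_fit <- function(x, y, cost, gamma) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  e1071::svm(x = as.matrix(x), y = y, kernel = "radial", cost = cost,
             gamma = gamma, scale = FALSE)
}

# Center/scale with training statistics; zero-spread features get unit scale.
fit_scaling <- function(x) {
  center <- vapply(x, mean, numeric(1))
  spread <- vapply(x, sd, numeric(1))
  spread[!is.finite(spread) | spread == 0] <- 1
  list(center = center, scale = spread)
}

apply_scaling <- function(x, scaling) {
  sweep(sweep(as.matrix(x), 2, scaling$center, "-"), 2, scaling$scale, "/")
}

# Impute missing values (notably f6 for single-peak bouts) with training
# medians.
fit_imputation <- function(x) {
  vapply(x, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
}

apply_imputation <- function(x, medians) {
  for (nm in names(x)) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- medians[[nm]]
  }
  x
}

#' Cross-validate the RBF-SVM bout classifier
#'
#' Fivefold stratified cross-validation: folds from
#' [make_stratified_folds()], an RBF-kernel SVM trained on four folds and
#' tested on the held-out fold, rotated over all folds, predictions pooled.
#' Feature scaling and missing-value imputation are fit on the training
#' folds only.
#'
#' @param data A [labeled_bout_set()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment is content-keyed and
#'   deterministic; the seed is kept for interface stability).
#' @param feature_subset Feature names to use (default all 16).
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` uses
#'   1/n_features on standardized data.
#' @return A `cv_report`: `fold_assignments`, `fold_accuracy`,
#'   `pooled_accuracy`, `mean_fold_accuracy`, `confusion`, `predictions`.
#' @export
cross_validate <- function(data, folds = 5, seed = 1,
                           feature_subset = feature_names(), cost = 1,
                           gamma = NULL) {
  stopifnot(inherits(data, "labeled_bout_set"))
  assignment <- make_stratified_folds(data, folds, feature_subset)
  X <- data$features[feature_subset]
  y <- data$labels
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assignment != f
    medians <- fit_imputation(X[tr, , drop = FALSE])
    Xtr <- apply_imputation(X[tr, , drop = FALSE], medians)
    Xte <- apply_imputation(X[!tr, , drop = FALSE], medians)
    scaling <- fit_scaling(Xtr)
    fit <- svm_fit(apply_scaling(Xtr, scaling), y[tr], cost, gamma)
    p <- predict(fit, apply_scaling(Xte, scaling))
    pred[!tr] <- p
    fold_acc[f] <- mean(p == y[!tr])
  }
  structure(list(fold_assignments = assignment, fold_accuracy = fold_acc,
                 pooled_accuracy = mean(pred == y),
                 mean_fold_accuracy = mean(fold_acc),
                 confusion = table(truth = y, predicted = pred),
                 predictions = pred, n = length(y),
                 feature_subset = feature_subset),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> pooled accuracy %.3f (mean of folds %.3f) over %d bouts\n",
    x$pooled_accuracy, x$mean_fold_accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Rank parameters by single-feature cross-validated accuracy
#'
#' @param data A [labeled_bout_set()].
#' @param candidates Feature names to rank.
#' @param folds,seed,cost,gamma As in [cross_validate()].
#' @return Character vector of candidates, best first (ties keep canonical
#'   order).
#' @export
rank_parameters <- function(data, candidates = feature_names(), folds = 5,
                            seed = 1, cost = 1, gamma = NULL) {
  acc <- vapply(candidates, function(f) {
    cross_validate(data, folds, seed, feature_subset = f, cost = cost,
                   gamma = gamma)$pooled_accuracy
  }, numeric(1))
  candidates[order(-acc)]
}

#' Accuracy versus number of parameters
#'
#' Cross-validates nested feature subsets (the first k of `candidate_order`
#' for k = 1..K) and selects the smallest k whose accuracy is within
#' `tolerance` of the curve maximum — the point that maximizes performance
#' while minimizing the number of parameters.
#'
#' @param data A [labeled_bout_set()].
#' @param candidate_order Ranked feature names; `NULL` ranks them with
#'   [rank_parameters()].
#' @param folds,seed,cost,gamma As in [cross_validate()].
#' @param tolerance Accuracy slack (fraction) for the minimality rule.
#' @return A `parameter_selection`: `candidate_order`, `accuracy` (named by
#'   k), `selected_k`, `tolerance`.
#' @export
select_parameters <- function(data, candidate_order = NULL, folds = 5,
                              seed = 1, cost = 1, gamma = NULL,
                              tolerance = 0.005) {
  if (is.null(candidate_order)) {
    candidate_order <- rank_parameters(data, folds = folds, seed = seed,
                                       cost = cost, gamma = gamma)
  }
  if (length(candidate_order) < 2) stopf("need at least 2 candidates")
  acc <- vapply(seq_along(candidate_order), function(k) {
    cross_validate(data, folds, seed,
                   feature_subset = candidate_order[seq_len(k)],
                   cost = cost, gamma = gamma)$pooled_accuracy
  }, numeric(1))
  names(acc) <- seq_along(candidate_order)
  selected_k <- min(which(acc >= max(acc) - tolerance))
  structure(list(candidate_order = candidate_order, accuracy = acc,
                 selected_k = selected_k, tolerance = tolerance),
            class = "parameter_selection")
}

#' Train the RBF-SVM bout classifier
#'
#' Features are median-imputed and centered/scaled on the training data; an
#' RBF-kernel SVM draws the decision boundary. Everything needed to classify
#' new bouts identically across sessions (feature subset, imputation
#' medians, scaling, fitted model) is stored.
#'
#' @param data A [labeled_bout_set()].
#' @param feature_subset Feature names; the default is the five-parameter
#'   virtual-prey set.
#' @param cost,gamma Hyperparameters (see [cross_validate()]).
#' @return A `bout_classifier`.
#' @export
train_bout_classifier <- function(data,
                                  feature_subset = feature_names()[1:5],
                                  cost = 1, gamma = NULL) {
  stopifnot(inherits(data, "labeled_bout_set"))
  if (nlevels(droplevels(data$labels)) < 2) {
    stopf("training data must contain both classes")
  }
  X <- data$features[feature_subset]
  degenerate <- vapply(X, function(col) {
    v <- var(col, na.rm = TRUE)
    !is.finite(v) || v == 0
  }, logical(1))
  if (any(degenerate)) {
    warnf("dropping zero-variance feature(s): %s",
          paste(feature_subset[degenerate], collapse = ", "))
    feature_subset <- feature_subset[!degenerate]
    X <- X[feature_subset]
  }
  medians <- fit_imputation(X)
  X <- apply_imputation(X, medians)
  scaling <- fit_scaling(X)
  fit <- svm_fit(apply_scaling(X, scaling), data$labels, cost, gamma)
  train_pred <- predict(fit, apply_scaling(X, scaling))
  structure(list(feature_subset = feature_subset, scaling = scaling,
                 imputation_medians = medians,
                 hyperparams = list(cost = cost,
                                    gamma = gamma %||% 1 / ncol(X)),
                 model = fit,
                 training_counts = table(data$labels),
                 training_predictions = train_pred,
                 training_accuracy = mean(train_pred == data$labels),
                 schema = classifier_schema()),
            class = "bout_classifier")
}

classifier_schema <- function() "preybout/bout_classifier/1"

#' @export
print.bout_classifier <- function(x, ...) {
  cat(sprintf(
    "<bout_classifier> RBF-SVM on %d features; trained on %s (accuracy %.3f)\n",
    length(x$feature_subset),
    paste(sprintf("%d %s", x$training_counts, names(x$training_counts)),
          collapse = " + "),
    x$training_accuracy))
  invisible(x)
}

#' Classify bouts with a trained classifier
#'
#' @param clf A [train_bout_classifier()] result.
#' @param features data.frame of feature vectors (must contain the
#'   classifier's feature subset), or a [labeled_bout_set()].
#' @return Factor of predicted labels (`prey_capture` / `spontaneous`).
#' @export
classify_bouts <- function(clf, features) {
  stopifnot(inherits(clf, "bout_classifier"))
  if (inherits(features, "labeled_bout_set")) features <- features$features
  features <- as.data.frame(features)
  if (nrow(features) == 0) {
    return(factor(character(0), levels = c("prey_capture", "spontaneous")))
  }
  missing_cols <- setdiff(clf$feature_subset, names(features))
  if (length(missing_cols)) {
    stopf("schema error: feature column(s) absent: %s",
          paste(missing_cols, collapse = ", "))
  }
  X <- apply_imputation(features[clf$feature_subset],
                        clf$imputation_medians)
  predict(clf$model, apply_scaling(X, clf$scaling))
}

#' Prey-capture score of a trial
#'
#' Percentage of trial time spent in bouts classified as prey capture.
#'
#' @param bouts data.frame with `start_frame`, `end_frame` (half-open) and a
#'   `label` column.
#' @param trial_frames Total frames in the trial.
#' @return Score in percent (0 when no prey-capture bouts).
#' @export
prey_capture_score <- function(bouts, trial_frames) {
  if (!is_count(trial_frames) || trial_frames <= 0) {
    stopf("trial_frames must be a positive count")
  }
  if (nrow(bouts) == 0) return(0)
  if (any(bouts$start_frame < 1) || any(bouts$end_frame > trial_frames + 1)) {
    stopf("bouts extend outside the trial")
  }
  prey <- bouts[bouts$label == "prey_capture", , drop = FALSE]
  100 * sum(prey$end_frame - prey$start_frame) / trial_frames
}

#' Exclusion rule for unresponsive larvae
#'
#' Larvae whose prey-capture score for the reference stimulus falls below
#' `min_score` percent are excluded from tuning analyses (the screening rule
#' used with the 3-degree stimulus).
#'
#' @param scores data.frame with `larva`, `condition`, `score`.
#' @param reference_condition Condition defining responsiveness.
#' @param min_score Minimum score in percent (default 30).
#' @return `scores` with excluded larvae removed.
#' @export
exclude_low_responders <- function(scores, reference_condition,
                                   min_score = 30) {
  ref <- scores[scores$condition == reference_condition, , drop = FALSE]
  bad <- unique(ref$larva[ref$score < min_score])
  scores[!(scores$larva %in% bad), , drop = FALSE]
}

normalize_by_larva_max <- function(df, value_col) {
  split_rows <- split(seq_len(nrow(df)), df$larva)
  drop <- character(0)
  for (lv in names(split_rows)) {
    mx <- max(df[[value_col]][split_rows[[lv]]], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) {
      drop <- c(drop, lv)
    } else {
      df[[value_col]][split_rows[[lv]]] <-
        100 * df[[value_col]][split_rows[[lv]]] / mx
    }
  }
  if (length(drop)) {
    warnf("excluding larva(e) with no positive response: %s",
          paste(drop, collapse = ", "))
    df <- df[!(df$larva %in% drop), , drop = FALSE]
  }
  df
}

summarize_by_condition <- function(df, value_col) {
  conds <- split(df[[value_col]], df$condition)
  out <- data.frame(
    condition = names(conds),
    mean = vapply(conds, mean, numeric(1)),
    sem = vapply(conds, function(v) {
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(conds, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  # preserve the order conditions first appear in
  out[match(unique(as.character(df$condition)), out$condition), ,
      drop = FALSE]
}

#' Normalized stimulus tuning curve
#'
#' Each larva's scores are expressed as a percentage of that larva's maximum
#' score, then averaged across larvae per condition with the standard error
#' of the mean — the normalization used for dot-size (0.5-30 degrees) and
#' speed (6-480 degrees/s) tuning.
#'
#' @param scores data.frame with columns `larva`, `condition`, `score`; each
#'   larva needs at least one positive score (all-zero larvae are excluded
#'   with a warning).
#' @return data.frame `condition`, `mean`, `sem`, `n` (normalized percent).
#' @export
tuning_curve <- function(scores) {
  stopifnot(all(c("larva", "condition", "score") %in% names(scores)))
  df <- normalize_by_larva_max(scores, "score")
  if (nrow(df) == 0) stopf("no larvae with a positive score")
  summarize_by_condition(df, "score")
}
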