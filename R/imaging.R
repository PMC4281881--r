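as_movie_array <- function(movie) {
  if (inherits(movie, "fluorescence_movie")) movie <- movie$frames
  if (!(is.array(movie) && length(dim(movie)) == 3)) {
    stopf("movie must be a height x width x frames array")
  }
  movie
}

#' Sliding-percentile fluorescence baseline
#'
#' Per-pixel baseline for ΔF/F: at each frame, the given percentile of the
#' pixel's raw fluorescence over a centered sliding window (truncated at the
#' movie edges). The defaults — the 8th percentile over a 25-frame window —
#' estimate each pixel's value during a period of low activity without
#' knowing when stimuli occurred. Percentiles interpolate linearly between
#' order statistics (the convention of [stats::quantile()] type 7).
#'
#' @param movie height x width x frames array (or `fluorescence_movie`), or
#'   a single pixel trace (numeric vector), or a frames x pixels matrix.
#' @param window Window length in frames (must be < number of frames).
#' @param percentile Percentile in percent (default 8).
#' @return Baseline of the same shape as the input.
#' @export
sliding_percentile_baseline <- function(movie, window = 25, percentile = 8) {
  if (inherits(movie, "fluorescence_movie")) movie <- movie$frames
  if (is.numeric(movie) && is.null(dim(movie))) {
    out <- cpp_sliding_percentile(matrix(movie, ncol = 1), as.integer(window),
                                  percentile / 100)
    return(check_window(out[, 1], length(movie), window))
  }
  if (is.matrix(movie)) {
    check_window(NULL, nrow(movie), window)
    return(cpp_sliding_percentile(movie, as.integer(window),
                                  percentile / 100))
  }
  movie <- as_movie_array(movie)
  d <- dim(movie)
  check_window(NULL, d[3], window)
  traces <- t(matrix(movie, d[1] * d[2], d[3]))  # frames x pixels
  base <- cpp_sliding_percentile(traces, as.integer(window),
                                 percentile / 100)
  array(t(base), dim = d)
}

check_window <- function(out, n_frames, window) {
  if (window >= n_frames) {
    stopf("invalid window: %d frames >= movie length %d", window, n_frames)
  }
  out
}

#' Pixelwise ΔF/F
#'
#' `(raw - baseline) / baseline` per pixel per frame. Pixels whose baseline
#' is not strictly positive at every frame are masked (`NA`), counted and
#' warned about.
#'
#' @param movie Raw movie (height x width x frames array or
#'   `fluorescence_movie`).
#' @param baseline Baseline of the same shape; `NULL` computes the
#'   sliding-percentile baseline with `window` and `percentile`.
#' @param window,percentile Baseline parameters (see
#'   [sliding_percentile_baseline()]).
#' @return A `dff` object: `values` (same shape), `baseline_spec`, `masked`
#'   (logical height x width matrix).
#' @export
compute_dff <- function(movie, baseline = NULL, window = 25,
                        percentile = 8) {
  movie <- as_movie_array(movie)
  if (is.null(baseline)) {
    baseline <- sliding_percentile_baseline(movie, window, percentile)
  }
  if (!identical(dim(movie), dim(baseline))) {
    stopf("movie and baseline shapes differ")
  }
  d <- dim(movie)
  bad <- apply(baseline <= 0, c(1, 2), any)
  values <- (movie - baseline) / baseline
  if (any(bad)) {
    warnf("%d pixel(s) masked: baseline not strictly positive", sum(bad))
    values[array(bad, dim = d)] <- NA_real_
  }
  structure(list(values = values,
                 baseline_spec = list(window = window,
                                      percentile = percentile),
                 masked = bad),
            class = "dff")
}

as_dff_values <- function(x) {
  if (inherits(x, "dff")) x$values else as_movie_array(x)
}

#' Condition ratio map (response with / without stimulus)
#'
#' Maximum-intensity projections of ΔF/F, computed independently for the two
#' segments of a recording (for example before and after addition of prey to
#' the dish), are divided pixelwise. Pixels whose pre-segment maximum falls
#' below `floor` are masked to avoid dividing by noise.
#'
#' @param dff_pre,dff_post `dff` objects (or arrays) of equal spatial size.
#' @param floor Mask threshold on the pre-segment maximum ΔF/F.
#' @return Matrix of post/pre ratios (`NA` where masked).
#' @export
condition_ratio_map <- function(dff_pre, dff_post, floor = 0.05) {
  pre <- as_dff_values(dff_pre)
  post <- as_dff_values(dff_post)
  if (!identical(dim(pre)[1:2], dim(post)[1:2])) {
    stopf("spatial shapes differ")
  }
  pre_max <- apply(pre, c(1, 2), max)
  post_max <- apply(post, c(1, 2), max)
  ratio <- post_max / pre_max
  ratio[!is.finite(ratio) | pre_max < floor] <- NA_real_
  ratio
}

#' Mean ΔF/F response of a region of interest
#'
#' @param dff A `dff` object or ΔF/F array.
#' @param mask Logical height x width matrix (or pixel indices) selecting
#'   the ROI; must be non-empty and inside the frame.
#' @param condition Optional stimulus descriptor (dot size, speed,
#'   direction, paramecia/none) carried through to tuning analyses.
#' @param roi_name Optional ROI label.
#' @return An `roi_response`: `timecourse` (spatial mean per frame), `peak`
#'   (max of the time course), `condition`, `roi_name`.
#' @export
roi_response <- function(dff, mask, condition = NULL, roi_name = NULL) {
  values <- as_dff_values(dff)
  d <- dim(values)
  if (is.logical(mask)) {
    if (!identical(dim(mask), d[1:2])) stopf("mask shape mismatch")
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
    if (any(idx < 1 | idx > d[1] * d[2])) stopf("mask indices out of frame")
  }
  if (!length(idx)) stopf("empty ROI mask")
  px <- matrix(values, d[1] * d[2], d[3])[idx, , drop = FALSE]
  timecourse <- colMeans(px, na.rm = TRUE)
  structure(list(timecourse = timecourse, peak = max(timecourse),
                 condition = condition, roi_name = roi_name),
            class = "roi_response")
}

#' Normalized response tuning across larvae
#'
#' Per larva, condition responses (peak ΔF/F) are expressed as a percentage
#' of that larva's maximum response, then averaged per condition with SEM —
#' the normalization used for the size, speed and direction tuning of ROI
#' responses.
#'
#' @param responses data.frame with columns `larva`, `condition`,
#'   `response` (peak ΔF/F per trial/condition).
#' @return data.frame `condition`, `mean`, `sem`, `n`.
#' @export
response_tuning <- function(responses) {
  stopifnot(all(c("larva", "condition", "response") %in% names(responses)))
  df <- normalize_by_larva_max(responses, "response")
  if (nrow(df) == 0) stopf("no larvae with a positive response")
  summarize_by_condition(df, "response")
}

#' Jarque-Bera test of normality
#'
#' Tests whether skewness and excess kurtosis are jointly consistent with a
#' normal distribution; the statistic `n (S^2/6 + (K-3)^2/24)` is referred
#' to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample (n >= 3).
#' @return List with `statistic`, `p_value`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                skewness = NA_real_, kurtosis = NA_real_, n = n))
  }
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  jb <- n * (s^2 / 6 + (k - 3)^2 / 24)
  list(statistic = jb, p_value = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = s, kurtosis = k, n = n)
}

#' Two-group comparison with a normality gate
#'
#' The Jarque-Bera test is applied to each sample; when both are consistent
#' with normality (at `alpha`) the groups are compared with a two-sample
#' t-test, otherwise with the Wilcoxon rank sum test. Levene's variance test
#' (on absolute deviations from the group means) is reported alongside.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param alpha Significance level of the normality gate.
#' @param test `"auto"` applies the gate; `"t"` or `"wilcoxon"` force a
#'   test.
#' @param var_equal Passed to [stats::t.test()].
#' @return A `group_comparison`: `test`, `statistic`, `p_value`,
#'   `jarque_bera` (per sample), `levene`.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           test = c("auto", "t", "wilcoxon"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stopf("insufficient data: each sample needs n >= 3")
  }
  jb <- list(a = jarque_bera_test(a), b = jarque_bera_test(b))
  if (test == "auto") {
    normal <- !is.na(jb$a$p_value) && !is.na(jb$b$p_value) &&
      jb$a$p_value > alpha && jb$b$p_value > alpha
    test <- if (normal) "t" else "wilcoxon"
  }
  lev <- levene_report(a, b)
  if (test == "t") {
    ht <- t.test(a, b, var.equal = var_equal)
    res <- list(test = "t-test", statistic = unname(ht$statistic),
                p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    res <- list(test = "Wilcoxon rank sum", statistic = unname(ht$statistic),
                p_value = ht$p.value)
  }
  structure(c(res, list(jarque_bera = jb, levene = lev, alpha = alpha)),
            class = "group_comparison")
}

levene_report <- function(a, b) {
  values <- c(a, b)
  group <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(values, group, center = mean)
  list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"])
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  cat(sprintf("  normality (Jarque-Bera): p_a = %.3g, p_b = %.3g\n",
              x$jarque_bera$a$p_value, x$jarque_bera$b$p_value))
  cat(sprintf("  variance (Levene): p = %.3g\n", x$levene$p_value))
  invisible(x)
}

#' Detect translational drift in a movie
#'
#' Phase correlation of every frame against the first; warns when the
#' correlation peak moves more than `max_shift` pixels, indicating the movie
#' needs registration before ΔF/F analysis (registration itself is out of
#' scope here; input movies are assumed aligned).
#'
#' @param movie height x width x frames array or `fluorescence_movie`.
#' @param max_shift Tolerated shift in pixels.
#' @return data.frame `frame`, `dx`, `dy` (invisible warning side effect).
#' @export
detect_translation_drift <- function(movie, max_shift = 2) {
  movie <- as_movie_array(movie)
  d <- dim(movie)
  ref <- movie[, , 1]
  Fr <- fft(ref)
  shifts <- t(vapply(seq_len(d[3]), function(t) {
    Ft <- fft(movie[, , t])
    cp <- Fr * Conj(Ft)
    mag <- Mod(cp)
    mag[mag == 0] <- 1
    xc <- Re(fft(cp / mag, inverse = TRUE))
    pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
    dy <- pk[1] - 1
    dx <- pk[2] - 1
    if (dy > d[1] / 2) dy <- dy - d[1]
    if (dx > d[2] / 2) dx <- dx - d[2]
    c(dx, dy)
  }, numeric(2)))
  out <- data.frame(frame = seq_len(d[3]), dx = shifts[, 1], dy = shifts[, 2])
  if (any(abs(out$dx) > max_shift | abs(out$dy) > max_shift)) {
    warnf("translation drift exceeds %g px; register the movie first",
          max_shift)
  }
  out
}
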