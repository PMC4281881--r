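# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed` (NULL leaves
# the global stream untouched). Restores .Random.seed afterwards so seeded
# generators are referentially transparent.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %%
               .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Unit-normalized symmetric Gaussian kernel (odd length).
gaussian_kernel <- function(sigma, half_width = ceiling(3 * sigma)) {
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Moving average with edge values carried outward (no NA at the borders).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L || length(x) < 2L) return(x)
  n <- length(x)
  hw <- window %/% 2
  padded <- c(rep(x[1], hw), x, rep(x[n], window - hw - 1L))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 1))[
    seq.int(window, length.out = n)]
}

# Resample an ordered polyline (n x 2 matrix) to `n_out` points equally
# spaced in arc length.
resample_polyline <- function(pts, n_out) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(pts[1, ], each = n_out), ncol = 2))
  target <- seq(0, total, length.out = n_out)
  cbind(approx(s, pts[, 1], xout = target, ties = "ordered")$y,
        approx(s, pts[, 2], xout = target, ties = "ordered")$y)
}

arc_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# Alternating extrema of a 1-D signal with hysteresis: successive recorded
# extrema differ by at least `min_swing`, suppressing noise wiggles on
# plateaus. The starting point is not recorded. Returns indices in order.
alternating_extrema <- function(x, min_swing) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  min_i <- 1L; max_i <- 1L
  dir <- 0L  # +1 tracking a running max, -1 a running min, 0 undecided
  cand_i <- 1L
  for (i in 2:n) {
    v <- x[i]
    if (dir == 0L) {
      if (v <= x[min_i]) min_i <- i
      if (v >= x[max_i]) max_i <- i
      if (x[max_i] - x[min_i] >= min_swing) {
        # direction of the first swing decides which extreme we track next
        if (max_i > min_i) { dir <- 1L; cand_i <- max_i }
        else { dir <- -1L; cand_i <- min_i }
      }
    } else if (dir == 1L) {
      if (v > x[cand_i]) {
        cand_i <- i
      } else if (x[cand_i] - v >= min_swing) {
        idx <- c(idx, cand_i)
        cand_i <- i; dir <- -1L
      }
    } else {
      if (v < x[cand_i]) {
        cand_i <- i
      } else if (v - x[cand_i] >= min_swing) {
        idx <- c(idx, cand_i)
        cand_i <- i; dir <- 1L
      }
    }
  }
  # the final candidate is never confirmed by a reversal, so it is dropped:
  # partial trailing swings would otherwise bias amplitude estimates
  idx
}
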