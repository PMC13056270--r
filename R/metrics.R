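#' Inter-onset intervals of an event sequence
#'
#' @param seq an `event_seq` or a strictly increasing numeric vector of event
#'   times (ms).
#' @return Numeric vector of interval durations (ms), one fewer than the
#'   number of events.
#' @export
intervals <- function(seq) {
  x <- as.numeric(seq)
  if (length(x) < 2) stop("intervals: at least 2 events required")
  if (anyNA(x) || is.unsorted(x, strictly = TRUE))
    stop("intervals: event times must be strictly increasing")
  diff(x)
}

#' Rhythm ratios of successive intervals
#'
#' The rhythm ratio of two successive inter-onset intervals is
#' `r_k = i_k / (i_k + i_{k+1})`, a dimensionless value in (0, 1) capturing
#' their relative duration: 0.5 is isochrony (1:1), 2/3 is a long-short 2:1
#' pair, 1/3 a short-long 1:2 pair.
#'
#' @param iv numeric vector of positive interval durations (from
#'   [intervals()]), length >= 2.
#' @return Numeric vector of ratios, one fewer than the number of intervals.
#' @examples
#' rhythm_ratios(c(200, 100))  # 0.666...
#' @export
rhythm_ratios <- function(iv) {
  iv <- as.numeric(iv)
  if (length(iv) < 2) stop("rhythm_ratios: at least 2 intervals required")
  if (any(iv <= 0)) stop("rhythm_ratios: all intervals must be positive")
  n <- length(iv)
  iv[-n] / (iv[-n] + iv[-1])
}

#' Event sequence -> rhythm ratios convenience wrapper
#' @param seq an `event_seq` (>= 3 events).
#' @return Numeric vector of rhythm ratios.
#' @export
event_ratios <- function(seq) rhythm_ratios(intervals(seq))

#' Kernel density estimate of a ratio sample
#'
#' Gaussian-kernel density with Scott's-rule bandwidth
#' `sd(x) * n^(-1/5)`, evaluated at arbitrary grid points.
#'
#' @param ratios numeric sample in (0, 1) with at least 2 distinct values.
#' @param grid evaluation points (default 512 points spanning `[0, 1]`).
#' @return A data.frame with columns `ratio` and `density`.
#' @export
kde_density <- function(ratios, grid = seq(0, 1, length.out = 512)) {
  ratios <- as.numeric(ratios)
  n <- length(ratios)
  if (n < 2 || stats::sd(ratios) == 0)
    stop("kde_density: need >= 2 distinct ratio values (degenerate sample)")
  h <- stats::sd(ratios) * n^(-1 / 5)  # Scott's rule
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - ratios) / h)) / h,
                 numeric(1))
  data.frame(ratio = grid, density = dens)
}

#' The seven small-integer ratio targets
#'
#' Rhythm-ratio values of the categories 1:3, 1:2, 2:3, 1:1, 3:2, 2:1 and
#' 3:1. Inverse ratios (e.g. 1:2 and 2:1) are kept separate.
#' @return Named numeric vector of target rhythm ratios.
#' @export
integer_ratio_targets <- function() {
  c("1:3" = 1 / 4, "1:2" = 1 / 3, "2:3" = 2 / 5, "1:1" = 1 / 2,
    "3:2" = 3 / 5, "2:1" = 2 / 3, "3:1" = 3 / 4)
}

#' On-/off-integer bins around small-integer ratio targets
#'
#' Partitions a neighbourhood of each target ratio into an on-bin (the
#' central half of the target's segment) and two flanking off-bins. Segment
#' boundaries between adjacent targets sit at their midpoint; the outermost
#' targets mirror their inner half-width. Each bin is weighted by the inverse
#' of its width, so a uniform ratio distribution scores an on-fraction of
#' exactly 0.5 (the combined off-width equals the on-width per target).
#'
#' @param targets sorted, distinct target ratios; defaults to
#'   [integer_ratio_targets()].
#' @return An object of class `ratio_bins`: a data.frame with one row per
#'   target (`target`, segment `lo`/`hi`, on-bin `on_lo`/`on_hi`).
#' @export
build_bins <- function(targets = integer_ratio_targets()) {
  t <- as.numeric(targets)
  if (length(t) < 2) stop("build_bins: at least 2 targets required")
  if (is.unsorted(t, strictly = TRUE))
    stop("build_bins: targets must be sorted and distinct")
  k <- length(t)
  mid <- (t[-k] + t[-1]) / 2
  lo <- c(t[1] - (mid[1] - t[1]), mid)
  hi <- c(mid, t[k] + (t[k] - mid[k - 1]))
  on_lo <- t - (t - lo) / 2
  on_hi <- t + (hi - t) / 2
  out <- data.frame(target = t, lo = lo, hi = hi, on_lo = on_lo, on_hi = on_hi)
  if (!is.null(names(targets))) out$label <- names(targets)
  class(out) <- c("ratio_bins", "data.frame")
  out
}

#' Weighted on-integer fraction at one target ratio
#'
#' Counts ratios falling in the target's on-bin and its two flanking
#' off-bins, normalises each count by the corresponding total width
#' (on-width, combined off-width), and returns
#' `W_on / (W_on + W_off)`. A value near 1 means the ratio distribution is
#' concentrated on the target category; a uniform distribution scores 0.5.
#' Returns `NA` if no ratio falls in any of the three bins.
#'
#' @param ratios numeric rhythm-ratio sample.
#' @param target one of the bin targets (value, or a label such as `"1:1"`
#'   when the bins carry labels).
#' @param bins a `ratio_bins` object from [build_bins()].
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
on_integer_fraction <- function(ratios, target, bins = build_bins()) {
  stopifnot(inherits(bins, "ratio_bins"))
  if (is.character(target)) {
    if (is.null(bins$label) || !target %in% bins$label)
      stop("on_integer_fraction: unknown target label '", target, "'")
    row <- bins[bins$label == target, ]
  } else {
    i <- which(abs(bins$target - target) < 1e-9)
    if (length(i) != 1) stop("on_integer_fraction: 'target' is not one of the bin targets")
    row <- bins[i, ]
  }
  ratios <- as.numeric(ratios)
  n_on <- sum(ratios >= row$on_lo & ratios < row$on_hi)
  n_off <- sum((ratios >= row$lo & ratios < row$on_lo) |
                 (ratios >= row$on_hi & ratios < row$hi))
  w_on <- row$on_hi - row$on_lo
  w_off <- (row$on_lo - row$lo) + (row$hi - row$on_hi)
  W_on <- n_on / w_on
  W_off <- n_off / w_off
  if (W_on + W_off == 0) return(NA_real_)
  W_on / (W_on + W_off)
}

#' Spacing-based differential entropy estimate
#'
#' Ebrahimi et al.'s boundary-corrected variant of the Vasicek spacing
#' estimator with window `m = floor(sqrt(n))`:
#' `H = mean(log(n * (x_(i+m) - x_(i-m)) / (c_i * m)))` over the order
#' statistics, with indices clipped to the sample range and the boundary
#' weights `c_i` interpolating between 1 and 2. For distributions supported
#' on (0, 1) the maximum is 0 nats, attained by the uniform. Degenerate
#' (near-constant) samples return `-Inf`: if more than half of the window
#' spacings are exactly zero the estimate is short-circuited, and any zero
#' spacing otherwise contributes `log(0) = -Inf` to the mean.
#'
#' @param ratios numeric sample, length >= 10.
#' @return Entropy estimate in nats, possibly `-Inf`.
#' @examples
#' differential_entropy(runif(1000))         # close to 0
#' differential_entropy(rep(0.5, 1000))      # -Inf
#' @export
differential_entropy <- function(ratios) {
  x <- as.numeric(ratios)
  n <- length(x)
  if (n < 10) stop("differential_entropy: at least 10 values required")
  m <- floor(sqrt(n))
  xs <- sort(x)
  i <- seq_len(n)
  sp <- xs[pmin(i + m, n)] - xs[pmax(i - m, 1L)]
  if (mean(sp == 0) > 0.5) return(-Inf)
  ci <- ifelse(i <= m, 1 + (i - 1) / m,
               ifelse(i >= n - m + 1, 1 + (n - i) / m, 2))
  mean(log(n * sp / (ci * m)))
}

#' One-row summary of rhythm metrics for an event sequence
#'
#' Computes the rhythm ratios of `seq` and returns the differential entropy
#' together with the on-integer fraction at each of the seven small-integer
#' ratio categories, in the column layout
#' `n_intervals, entropy, frac_1_3, frac_1_2, frac_2_3, frac_1_1, frac_3_2,
#' frac_2_1, frac_3_1`.
#'
#' @param seq an `event_seq` (or numeric event times) with >= 12 events.
#' @param bins a `ratio_bins` object.
#' @return A one-row data.frame.
#' @export
sequence_metrics <- function(seq, bins = build_bins()) {
  r <- event_ratios(seq)
  fr <- vapply(bins$target, function(t) on_integer_fraction(r, t, bins),
               numeric(1))
  labs <- gsub(":", "_", bins$label)
  out <- data.frame(n_intervals = length(r) + 1L,
                    entropy = differential_entropy(r))
  out[paste0("frac_", labs)] <- as.list(fr)
  out
}
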