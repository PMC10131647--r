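# Mean-shift change-point detection: two-region residual-sum-of-squares
# splitting and penalised binary segmentation, the detector behind the
# per-segment turn boundaries.

#' Best single mean-shift split of a signal
#'
#' Finds the split size `k` minimising
#' `RSS(x[1..k]) + RSS(x[(k+1)..T])`, where `RSS` is the sum of squared
#' deviations of a region from its own mean — the point at which the mean of
#' the signal changes most significantly. Ties break toward the smallest
#' `k`.
#'
#' @param x numeric vector, length >= 2, no `NA`s.
#' @return list with `index` (the size of the left region, in `1..T-1`) and
#'   `cost` (the two-region RSS at the optimum).
#' @export
best_single_split <- function(x) {
  n <- length(x)
  if (n < 2L) stop("best_single_split needs at least 2 samples")
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  k <- seq_len(n - 1L)
  left <- s2[k] - s1[k]^2 / k
  right <- (s2[n] - s2[k]) - (s1[n] - s1[k])^2 / (n - k)
  cost <- pmax(left, 0) + pmax(right, 0)
  i <- which.min(cost)
  list(index = i, cost = cost[i])
}

rss_of <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2)
}

#' Penalised multiple change-point detection (binary segmentation)
#'
#' Recursively applies [best_single_split()], accepting a split only when it
#' reduces the residual sum of squares by more than `penalty` (plus a small
#' numerical floor proportional to the total RSS, so that floating-point
#' jitter on an exactly constant signal is never segmented). The default
#' penalty is BIC-style, `3 * sigma^2 * log(T)`, with `sigma` estimated
#' robustly from the median absolute first difference.
#'
#' @param x numeric vector, no `NA`s.
#' @param penalty cost of adding one change point; `NULL` for the default.
#' @param min_size smallest admissible region length.
#' @return object of class `change_point_result`: `indices` (ordered split
#'   sizes, boundary after sample `k`), `cost` (RSS of the induced
#'   piecewise-constant-mean fit), `penalty` (the value used).
#' @export
detect_change_points <- function(x, penalty = NULL, min_size = 1L) {
  n <- length(x)
  stopifnot(n >= 2L, !anyNA(x))
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    penalty <- 3 * sigma^2 * log(n)
  }
  if (penalty < 0) stop("penalty must be non-negative")
  tol <- 1e-10 * rss_of(x) + 1e-12

  splits <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    lo <- seg[1]; hi <- seg[2]
    len <- hi - lo + 1L
    if (len < 2L * min_size) next
    xs <- x[lo:hi]
    bs <- best_split_constrained(xs, min_size)
    if (is.null(bs)) next
    gain <- rss_of(xs) - bs$cost
    if (gain > penalty + tol) {
      k <- lo - 1L + bs$index
      splits <- c(splits, k)
      queue <- c(queue, list(c(lo, k)), list(c(k + 1L, hi)))
    }
  }
  splits <- sort(splits)
  segs <- segments_from_cps(splits, n)
  cost <- sum(vapply(seq_len(nrow(segs)),
                     function(i) rss_of(x[segs$start[i]:segs$end[i]]),
                     numeric(1)))
  structure(list(indices = splits, cost = cost, penalty = penalty),
            class = "change_point_result")
}

best_split_constrained <- function(xs, min_size) {
  n <- length(xs)
  if (n < 2L) return(NULL)
  bs <- best_single_split(xs)
  if (min_size > 1L) {
    s1 <- cumsum(xs); s2 <- cumsum(xs * xs)
    k <- seq.int(min_size, n - min_size)
    if (!length(k)) return(NULL)
    left <- s2[k] - s1[k]^2 / k
    right <- (s2[n] - s2[k]) - (s1[n] - s1[k])^2 / (n - k)
    cost <- pmax(left, 0) + pmax(right, 0)
    i <- which.min(cost)
    bs <- list(index = k[i], cost = cost[i])
  }
  bs
}

#' Segments induced by a set of change points
#' @param indices ordered split sizes (boundary after sample `k`).
#' @param n signal length.
#' @return data.frame with 1-based inclusive `start` and `end` per segment.
#' @export
segments_from_cps <- function(indices, n) {
  data.frame(start = c(1L, indices + 1L), end = c(indices, n))
}

#' @export
print.change_point_result <- function(x, ...) {
  cat(sprintf("<change_point_result> %d change points, fit RSS %.4g (penalty %.4g)\n",
              length(x$indices), x$cost, x$penalty))
  invisible(x)
}
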