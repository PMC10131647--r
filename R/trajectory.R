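#' Marker trajectory
#'
#' One labelled retroreflective marker's 3D position time series in the lab
#' frame. The lab frame convention throughout the package is: `x` along the
#' walkway, `z` vertical (gravity axis), units metres. Occluded frames are
#' kept as `NA` rows — they are never silently zeroed.
#'
#' @param label marker name, e.g. `"head_1"` or `"toe_l"`.
#' @param positions numeric T x 3 matrix of positions in metres.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return an object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(label, positions, fs, t0 = 0) {
  positions <- as.matrix(positions)
  stopifnot(is.character(label), length(label) == 1L)
  if (ncol(positions) != 3L)
    stop("positions must have exactly 3 columns (x, y, z)")
  if (nrow(positions) < 2L)
    stop("a marker trajectory needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(label = label, positions = positions, fs = as.numeric(fs),
         t0 = as.numeric(t0)),
    class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  n_na <- sum(!stats::complete.cases(x$positions))
  cat(sprintf("<marker_trajectory> %s: %d frames @ %g Hz, %d occluded\n",
              x$label, nrow(x$positions), x$fs, n_na))
  invisible(x)
}

#' Number of frames of a marker trajectory
#' @param x a `marker_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(x) nrow(x$positions)

#' Time vector of a marker trajectory
#' @param x a `marker_trajectory`.
#' @return numeric vector of sample times in seconds.
#' @export
time_vector <- function(x) x$t0 + (seq_len(nrow(x$positions)) - 1L) / x$fs

#' Which frames of a trajectory are valid (non-occluded)
#' @param x a `marker_trajectory`.
#' @return logical vector, `TRUE` where all three coordinates are present.
#' @export
valid_frames <- function(x) stats::complete.cases(x$positions)

#' Interpolate short occlusion gaps
#'
#' Linearly interpolates runs of missing samples no longer than `max_gap`
#' frames (default 10 frames = 50 ms at 200 Hz). Longer gaps are left as
#' `NA`; downstream turn detection discards turns that enclose invalid
#' frames rather than imputing them.
#'
#' @param x a `marker_trajectory`.
#' @param max_gap longest gap, in frames, that is bridged.
#' @return the trajectory with short gaps filled.
#' @export
interpolate_gaps <- function(x, max_gap = 10L) {
  ok <- valid_frames(x)
  if (all(ok)) return(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- x$positions
  idx <- which(ok)
  for (j in which(!r$values)) {
    if (r$lengths[j] > max_gap) next
    a <- starts[j]; b <- ends[j]
    # gaps touching either end of the trial cannot be bridged
    if (a == 1L || b == nrow(pos)) next
    for (k in 1:3) {
      pos[a:b, k] <- stats::approx(x = c(a - 1L, b + 1L),
                                   y = pos[c(a - 1L, b + 1L), k],
                                   xout = a:b)$y
    }
  }
  x$positions <- pos
  x
}
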