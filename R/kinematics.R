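#' Unwrap an angle sequence (degrees)
#'
#' Removes 360-degree jumps so that successive samples differ by less than
#' 180 degrees, keeping continuous rotations (e.g. 170 -> 190) continuous.
#' `NA` gaps are skipped: unwrapping continues across them using the valid
#' samples on either side.
#'
#' @param x numeric vector of angles in degrees, possibly with `NA`s.
#' @return unwrapped angles, same length, `NA`s preserved.
#' @export
unwrap_deg <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) > 1L) {
    corr <- cumsum(round(diff(v) / 360)) * 360
    v[-1L] <- v[-1L] - corr
  }
  x[ok] <- v
  x
}

# zero-phase 4th-order Butterworth low-pass; NA runs are filtered separately
# and runs too short for stable edge padding are passed through unfiltered.
# Odd-reflection padding suppresses the startup transients of the raw
# forward-backward filter.
lowpass_signal <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) stop("filter cutoff must be below the Nyquist rate fs/2")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  pad_target <- as.integer(ceiling(3 * fs / cutoff))
  y <- x
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    n <- b - a + 1L
    pad <- min(pad_target, n - 1L)
    if (pad < 9L) next
    xs <- x[a:b]
    xp <- c(2 * xs[1] - xs[(pad + 1L):2L], xs,
            2 * xs[n] - xs[(n - 1L):(n - pad)])
    # filter about the padded start/end values so the zero-state transient
    # acts on a signal that starts at zero (exact for constants)
    filt0 <- function(v) {
      v0 <- v[1]
      as.numeric(signal::filter(bf, v - v0)) + v0
    }
    yp <- rev(filt0(rev(filt0(xp))))
    y[a:b] <- yp[(pad + 1L):(pad + n)]
  }
  y
}

#' Segment yaw from a marker cluster
#'
#' Per frame, fits the least-squares rigid rotation (orthogonal Procrustes /
#' Kabsch) taking the cluster's configuration at the first valid frame to
#' the current frame, and extracts the yaw angle (Euler z in a z-y-x
#' sequence, i.e. `atan2(R[2,1], R[1,1])`). The result is unwrapped over
#' time. Occlusion gaps up to `max_gap` frames are linearly interpolated
#' first; frames still missing any cluster marker are `NA`.
#'
#' @param markers list of at least 3 [marker_trajectory()] objects on one
#'   rigid segment.
#' @param segment segment name stored in the result (defaults to the common
#'   prefix of the marker labels).
#' @param max_gap occlusion gaps up to this many frames are interpolated.
#' @param reference optional m x 3 matrix giving the cluster configuration
#'   (marker rows, in marker order) that defines zero yaw — e.g. from a
#'   static calibration frame. Defaults to the first valid frame, which
#'   makes yaw relative to the trial's initial heading.
#' @return an object of class `segment_yaw_signal`: fields `segment`,
#'   `yaw_deg` (length-T unwrapped, degrees, `NA` where undefined), `fs`.
#' @export
segment_yaw <- function(markers, segment = NULL, max_gap = 10L,
                        reference = NULL) {
  stopifnot(is.list(markers), length(markers) >= 3L)
  markers <- lapply(markers, interpolate_gaps, max_gap = max_gap)
  fs <- markers[[1]]$fs
  Tn <- n_frames(markers[[1]])
  stopifnot(all(vapply(markers, n_frames, integer(1)) == Tn))
  if (is.null(segment))
    segment <- sub("_[0-9]+$", "", markers[[1]]$label)
  m <- length(markers)

  ok <- Reduce(`&`, lapply(markers, valid_frames))
  if (!any(ok)) stop("no frame with all cluster markers valid")
  ref_idx <- which(ok)[1]

  # T x m coordinate matrices
  X <- vapply(markers, function(mk) mk$positions[, 1], numeric(Tn))
  Y <- vapply(markers, function(mk) mk$positions[, 2], numeric(Tn))
  Z <- vapply(markers, function(mk) mk$positions[, 3], numeric(Tn))
  A <- if (is.null(reference)) cbind(X[ref_idx, ], Y[ref_idx, ], Z[ref_idx, ])
       else as.matrix(reference)
  if (!all(dim(A) == c(m, 3L)))
    stop("reference must be an m x 3 matrix matching the marker count")
  A <- sweep(A, 2, colMeans(A))
  sv <- svd(A)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12) || sv[2] < 1e-9)
    stop("degenerate marker cluster: markers are collinear at the reference frame")

  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y); Zc <- Z - rowMeans(Z)
  # cross-covariance H(t) = A' B(t): each column of Hmat is one entry of H
  Hmat <- cbind(Xc %*% A, Yc %*% A, Zc %*% A)  # T x 9: (bx,by,bz) x (a1,a2,a3)

  yaw <- rep(NA_real_, Tn)
  for (t in which(ok)) {
    H <- matrix(Hmat[t, ], 3, 3, byrow = TRUE)   # rows: b-coord, cols: a-coord
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    yaw[t] <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  }
  structure(list(segment = segment, yaw_deg = unwrap_deg(yaw), fs = fs),
            class = "segment_yaw_signal")
}

#' @export
print.segment_yaw_signal <- function(x, ...) {
  cat(sprintf("<segment_yaw_signal> %s: %d frames @ %g Hz, range [%.1f, %.1f] deg\n",
              x$segment, length(x$yaw_deg), x$fs,
              min(x$yaw_deg, na.rm = TRUE), max(x$yaw_deg, na.rm = TRUE)))
  invisible(x)
}

#' Angular velocity of a yaw signal
#'
#' Low-pass filters the yaw signal (zero-phase 4th-order Butterworth,
#' default cutoff 6 Hz — turning dynamics live below 2 Hz, marker jitter
#' above) and differentiates it by central differences.
#'
#' @param yaw a [segment_yaw_signal] (or `list(yaw_deg=, fs=, segment=)`).
#' @param filter_cutoff_hz low-pass cutoff in Hz; must be below `fs / 2`.
#' @return an object of class `angular_velocity_signal`: fields `segment`,
#'   `omega_degps`, `fs`.
#' @export
angular_velocity <- function(yaw, filter_cutoff_hz = 6) {
  y <- lowpass_signal(yaw$yaw_deg, yaw$fs, filter_cutoff_hz)
  omega <- central_diff(y) * yaw$fs
  structure(list(segment = yaw$segment, omega_degps = omega, fs = yaw$fs),
            class = "angular_velocity_signal")
}

central_diff <- function(y) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  d[1] <- y[2] - y[1]
  d[n] <- y[n] - y[n - 1]
  d
}

#' Mean straight-walking gait speed
#'
#' Mean horizontal speed of the pelvis cluster centroid over all
#' straight-walking intervals, i.e. outside detected pelvis turns extended
#' by a guard band on both sides.
#'
#' @param pelvis_markers list of the pelvis [marker_trajectory()] objects.
#' @param turn_events list of [turn_event]s (or a data.frame with `start_s`,
#'   `end_s`) for the pelvis; may be empty if the trial has no turns.
#' @param guard_band_s guard band, in seconds, excluded around each turn.
#' @param filter_cutoff_hz low-pass cutoff for the centroid velocity.
#' @return gait speed in m/s.
#' @export
gait_speed <- function(pelvis_markers, turn_events = list(),
                       guard_band_s = 0.25, filter_cutoff_hz = 6) {
  fs <- pelvis_markers[[1]]$fs
  Tn <- n_frames(pelvis_markers[[1]])
  cx <- rowMeans(vapply(pelvis_markers, function(m) m$positions[, 1], numeric(Tn)))
  cy <- rowMeans(vapply(pelvis_markers, function(m) m$positions[, 2], numeric(Tn)))
  vx <- central_diff(lowpass_signal(cx, fs, filter_cutoff_hz)) * fs
  vy <- central_diff(lowpass_signal(cy, fs, filter_cutoff_hz)) * fs
  speed <- sqrt(vx^2 + vy^2)

  tw <- turn_windows(turn_events)
  tt <- (seq_len(Tn) - 1L) / fs
  straight <- rep(TRUE, Tn)
  straight[is.na(speed)] <- FALSE
  if (nrow(tw))
    for (i in seq_len(nrow(tw)))
      straight[tt >= tw$start_s[i] - guard_band_s &
               tt <= tw$end_s[i] + guard_band_s] <- FALSE
  straight[c(1L, Tn)] <- FALSE     # one-sided difference edges
  if (!any(straight))
    stop("no straight-walking interval outside the detected turns")
  mean(speed[straight])
}

turn_windows <- function(turn_events) {
  if (is.data.frame(turn_events)) return(turn_events[c("start_s", "end_s")])
  if (!length(turn_events))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(start_s = vapply(turn_events, `[[`, numeric(1), "start_s"),
             end_s = vapply(turn_events, `[[`, numeric(1), "end_s"))
}
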