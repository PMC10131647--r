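#' Turn event
#'
#' One detected turn of one body segment.
#'
#' @param segment segment name.
#' @param start_s,end_s turn boundaries in seconds (`start_s < end_s`).
#' @param magnitude_deg absolute yaw change between the boundaries.
#' @param direction sign of the yaw change (+1 or -1).
#' @param peak_omega_degps maximal absolute yaw rate inside the turn.
#' @return object of class `turn_event`.
#' @export
turn_event <- function(segment, start_s, end_s, magnitude_deg, direction,
                       peak_omega_degps) {
  stopifnot(start_s < end_s, magnitude_deg >= 0)
  structure(list(segment = segment, start_s = start_s, end_s = end_s,
                 magnitude_deg = magnitude_deg, direction = direction,
                 peak_omega_degps = peak_omega_degps),
            class = "turn_event")
}

#' @export
print.turn_event <- function(x, ...) {
  cat(sprintf("<turn_event> %s: %.2f-%.2f s, %.1f deg (dir %+d), peak %.1f deg/s\n",
              x$segment, x$start_s, x$end_s, x$magnitude_deg, x$direction,
              x$peak_omega_degps))
  invisible(x)
}

#' Turn events as a data.frame
#' @param events list of [turn_event]s.
#' @return data.frame with one row per event.
#' @export
turns_as_df <- function(events) {
  if (!length(events))
    return(data.frame(segment = character(0), start_s = numeric(0),
                      end_s = numeric(0), magnitude_deg = numeric(0),
                      direction = numeric(0), peak_omega_degps = numeric(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(segment = e$segment, start_s = e$start_s, end_s = e$end_s,
               magnitude_deg = e$magnitude_deg, direction = e$direction,
               peak_omega_degps = e$peak_omega_degps)))
}

#' Detect turns in a segment yaw signal
#'
#' Change points partition the yaw signal into regions of locally constant
#' mean; each region is classified as plateau (mean absolute yaw rate below
#' `plateau_omega_thresh`) or transition, and every maximal transition run
#' bounded by plateaus whose means differ by at least `min_turn_magnitude`
#' becomes one turn. By default the boundaries are then refined to the
#' points where the low-pass-filtered yaw crosses `refine_frac` (and
#' `1 - refine_frac`) of the plateau-to-plateau change, which localises the
#' onset to sub-change-point precision; `refine = FALSE` keeps the raw
#' bounding change points. Because the boundaries sit strictly inside the
#' smooth transition, the detected magnitude systematically underestimates
#' the nominal plateau difference.
#'
#' Occlusion-invalidated (`NA`) frames split the signal; a turn is only
#' reported when it lies entirely within one valid run, so turns containing
#' invalid frames are discarded rather than imputed.
#'
#' @param yaw a [segment_yaw_signal].
#' @param omega matching [angular_velocity_signal] (computed from `yaw` when
#'   omitted).
#' @param penalty change-point penalty, `NULL` for the default of
#'   [detect_change_points()].
#' @param min_turn_magnitude smallest plateau-to-plateau yaw change (deg)
#'   that counts as a turn; the paradigm only contains ~180 degree turns.
#' @param plateau_omega_thresh plateau classification threshold, deg/s.
#' @param refine,refine_frac boundary refinement (see above).
#' @param filter_cutoff_hz cutoff of the low-pass used for refinement and,
#'   when `omega` is omitted, for the yaw rate.
#' @return list of [turn_event]s ordered by start time (possibly empty).
#' @export
detect_turns <- function(yaw, omega = NULL, penalty = NULL,
                         min_turn_magnitude = 90, plateau_omega_thresh = 20,
                         refine = TRUE, refine_frac = 0.05,
                         filter_cutoff_hz = 6) {
  if (is.null(omega)) omega <- angular_velocity(yaw, filter_cutoff_hz)
  stopifnot(length(omega$omega_degps) == length(yaw$yaw_deg))
  fs <- yaw$fs
  x_all <- yaw$yaw_deg
  om_all <- abs(omega$omega_degps)
  xf_all <- lowpass_signal(x_all, fs, filter_cutoff_hz)

  events <- list()
  ok <- !is.na(x_all)
  r <- rle(ok)
  run_ends <- cumsum(r$lengths); run_starts <- run_ends - r$lengths + 1L
  for (j in which(r$values)) {
    lo <- run_starts[j]; hi <- run_ends[j]
    if (hi - lo + 1L < 4L) next
    ev <- detect_turns_run(x_all[lo:hi], om_all[lo:hi], xf_all[lo:hi],
                           fs, lo, yaw$segment, penalty,
                           min_turn_magnitude, plateau_omega_thresh,
                           refine, refine_frac)
    events <- c(events, ev)
  }
  if (!length(events)) message("detect_turns: no turn detected for segment ",
                               yaw$segment)
  events[order(vapply(events, `[[`, numeric(1), "start_s"))]
}

detect_turns_run <- function(x, om, xf, fs, offset, segment, penalty,
                             min_turn_magnitude, plateau_omega_thresh,
                             refine, refine_frac) {
  cp <- detect_change_points(x, penalty = penalty)
  segs <- segments_from_cps(cp$indices, length(x))
  ns <- nrow(segs)
  # omega is NA on the one sample flanking an occlusion gap (central
  # differences); ignore those samples in the classification
  mean_om <- vapply(seq_len(ns), function(i)
    mean(om[segs$start[i]:segs$end[i]], na.rm = TRUE), numeric(1))
  # a segment with no valid omega sample (lone sample at a gap edge) cannot
  # bound a turn: classify it as transition
  mean_om[!is.finite(mean_om)] <- Inf
  plateau <- mean_om < plateau_omega_thresh
  if (sum(plateau) < 2L) return(list())

  # collapse consecutive same-class segments into alternating runs
  rr <- rle(plateau)
  nr <- length(rr$values)
  seg_hi <- cumsum(rr$lengths)
  seg_lo <- seg_hi - rr$lengths + 1L
  run_start <- segs$start[seg_lo]
  run_end <- segs$end[seg_hi]
  run_plateau <- rr$values
  # plateau level: median of the filtered yaw over the plateau run — robust
  # to slow transition tails that change-point segments may attach to it
  run_level <- vapply(seq_len(nr), function(i)
    stats::median(xf[run_start[i]:run_end[i]]), numeric(1))

  events <- list()
  for (i in seq_len(nr)) {
    if (run_plateau[i] || i == 1L || i == nr) next
    mu_pre <- run_level[i - 1L]; mu_post <- run_level[i + 1L]
    delta <- mu_post - mu_pre
    if (abs(delta) < min_turn_magnitude) next
    a <- run_start[i]; b <- run_end[i]
    if (refine) {
      sgn <- sign(delta)
      idx <- run_start[i - 1L]:run_end[i + 1L]
      hit <- which((xf[idx] - mu_pre) * sgn >= refine_frac * abs(delta))
      if (length(hit)) a <- idx[hit[1L]]
      hit2 <- which((mu_post - xf[idx]) * sgn >= refine_frac * abs(delta))
      if (length(hit2)) b <- idx[hit2[length(hit2)]]
    }
    if (b <= a) next
    events[[length(events) + 1L]] <- turn_event(
      segment,
      start_s = (offset + a - 2L) / fs,
      end_s = (offset + b - 2L) / fs,
      magnitude_deg = abs(xf[b] - xf[a]), direction = sign(delta),
      peak_omega_degps = max(om[a:b], na.rm = TRUE))
  }
  events
}
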