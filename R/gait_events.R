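# Foot-contact detection from heel/toe marker vertical velocities:
# initial contact at prominent local minima of the toe vertical velocity,
# final contact at prominent local maxima of the heel vertical velocity.

#' Local peaks with a prominence criterion
#'
#' Finds interior local maxima, computes each peak's topographic prominence
#' (height above the higher of the two valleys separating it from higher
#' terrain or the signal edge), discards peaks below `min_prominence`, and
#' greedily suppresses peaks closer than `min_distance` samples to a more
#' prominent one.
#'
#' @param v numeric signal.
#' @param min_prominence prominence threshold, in signal units.
#' @param min_distance minimal spacing between kept peaks, in samples.
#' @return data.frame with `index` and `prominence`, ordered by index.
#' @export
find_peaks <- function(v, min_prominence = 0, min_distance = 1L) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(data.frame(index = integer(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left <- if (i > 1L) v[1:(i - 1L)] else numeric(0)
    higher_l <- which(left >= h)
    lmin <- min(left[if (length(higher_l)) (max(higher_l) + 1L):(i - 1L) else seq_along(left)])
    right <- if (i < n) v[(i + 1L):n] else numeric(0)
    higher_r <- which(right >= h)
    rmin <- min(right[if (length(higher_r)) 1L:(min(higher_r) - 1L) else seq_along(right)])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1L && min_distance > 1L) {
    ord <- order(-prom)
    taken <- logical(0); kept <- integer(0)
    for (o in ord) {
      if (!length(kept) || all(abs(cand[o] - cand[kept]) >= min_distance))
        kept <- c(kept, o)
    }
    kept <- sort(kept)
    cand <- cand[kept]; prom <- prom[kept]
  }
  data.frame(index = cand, prominence = prom)
}

#' Detect foot contacts from heel and toe markers
#'
#' Computes low-pass-filtered vertical (z) velocities by central
#' differences; initial contacts are prominent local minima of the toe
#' vertical velocity and final contacts are prominent local maxima of the
#' heel vertical velocity. Extrema below `min_prominence` (m/s) or closer
#' than `min_step_interval` to a more prominent same-kind event are
#' suppressed. If two same-kind events still occur consecutively for the
#' foot, the less prominent one is dropped with a warning so that initial
#' and final contacts alternate.
#'
#' @param heel,toe [marker_trajectory()] objects of one foot.
#' @param foot `"left"` or `"right"` (inferred from a `_l`/`_r` label suffix
#'   when omitted).
#' @param min_prominence prominence threshold in m/s.
#' @param min_step_interval minimal spacing of same-kind events, seconds.
#' @param filter_cutoff_hz low-pass cutoff for the vertical velocity.
#' @return data.frame with `foot`, `kind` (`initial_contact` /
#'   `final_contact`), `time_s`, `prominence`, ordered by time; empty (with
#'   a message) when the trajectories are shorter than one gait cycle.
#' @export
detect_contacts <- function(heel, toe, foot = NULL, min_prominence = 0.2,
                            min_step_interval = 0.3, filter_cutoff_hz = 10) {
  stopifnot(heel$fs == toe$fs, n_frames(heel) == n_frames(toe))
  fs <- heel$fs
  if (is.null(foot)) {
    foot <- if (grepl("_l$", heel$label)) "left"
            else if (grepl("_r$", heel$label)) "right"
            else stop("cannot infer foot from label '", heel$label,
                      "'; pass foot explicitly")
  }
  empty <- data.frame(foot = character(0), kind = character(0),
                      time_s = numeric(0), prominence = numeric(0))
  if (n_frames(heel) < fs) {   # shorter than ~one gait cycle
    message("detect_contacts: trajectory too short for gait events")
    return(empty)
  }
  min_dist <- as.integer(round(min_step_interval * fs))
  vz <- function(m) central_diff(lowpass_signal(m$positions[, "z"], fs,
                                                filter_cutoff_hz)) * fs
  v_toe <- vz(toe)
  v_heel <- vz(heel)
  v_toe[is.na(v_toe)] <- 0
  v_heel[is.na(v_heel)] <- 0
  ic <- find_peaks(-v_toe, min_prominence, min_dist)
  fc <- find_peaks(v_heel, min_prominence, min_dist)
  ev <- rbind(
    if (nrow(ic)) data.frame(foot = foot, kind = "initial_contact",
                             time_s = heel$t0 + (ic$index - 1L) / fs,
                             prominence = ic$prominence) else empty,
    if (nrow(fc)) data.frame(foot = foot, kind = "final_contact",
                             time_s = heel$t0 + (fc$index - 1L) / fs,
                             prominence = fc$prominence) else empty)
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  repair_alternation(ev)
}

# drop the less prominent of two consecutive same-kind events (per foot)
repair_alternation <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  repeat {
    dup <- which(ev$kind[-1L] == ev$kind[-nrow(ev)])
    if (!length(dup)) break
    i <- dup[1L]
    drop <- if (ev$prominence[i] < ev$prominence[i + 1L]) i else i + 1L
    warning(sprintf(
      "dropping %s %s at %.3f s to restore initial/final contact alternation",
      ev$foot[drop], ev$kind[drop], ev$time_s[drop]), call. = FALSE)
    ev <- ev[-drop, ]
  }
  rownames(ev) <- NULL
  ev
}

#' Detect contacts for both feet of a trial
#' @param trial a [trial_record()].
#' @param ... passed to [detect_contacts()].
#' @return combined event data.frame ordered by time.
#' @export
trial_contacts <- function(trial, ...) {
  ev <- rbind(
    detect_contacts(trial$markers[["heel_l"]], trial$markers[["toe_l"]],
                    foot = "left", ...),
    detect_contacts(trial$markers[["heel_r"]], trial$markers[["toe_r"]],
                    foot = "right", ...))
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ev
}

#' Count steps inside a time window
#'
#' Number of initial contacts (both feet pooled) falling in the half-open
#' window `[start_s, end_s)` — half-open so that adjacent phases never
#' double-count a contact.
#'
#' @param events gait-event data.frame (see [detect_contacts()]).
#' @param window numeric length-2 vector `c(start_s, end_s)`.
#' @return integer step count.
#' @export
steps_in_window <- function(events, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  ic <- events$time_s[events$kind == "initial_contact"]
  sum(ic >= window[1] & ic < window[2])
}
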