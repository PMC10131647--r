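# General, segmental and intersegmental turning measures, per turn and
# averaged per trial/condition.

.PAIRS <- list(c("sternum", "head"), c("pelvis", "head"), c("pelvis", "sternum"))
pair_name <- function(p) paste(p[1], p[2], sep = "_")

#' Match turn events across the three segments
#'
#' Greedily matches head, sternum and pelvis [turn_event]s into per-turn
#' triples: for each head turn (in time order) the nearest unused sternum
#' and pelvis turns whose start lies within `max_onset_gap` seconds and
#' whose direction agrees. Turns that cannot be completed into a triple are
#' dropped with a message — intersegmental measures are only defined where
#' all three segments turned.
#'
#' @param events_by_segment named list (`head`, `sternum`, `pelvis`) of
#'   [turn_event] lists.
#' @param max_onset_gap largest admissible start-time difference, seconds.
#' @return list of triples, each a named list of the three matched events.
#' @export
match_turns <- function(events_by_segment, max_onset_gap = 1.5) {
  stopifnot(all(c("head", "sternum", "pelvis") %in% names(events_by_segment)))
  head_ev <- events_by_segment$head
  used <- list(sternum = logical(length(events_by_segment$sternum)),
               pelvis = logical(length(events_by_segment$pelvis)))
  pick <- function(seg, ref) {
    evs <- events_by_segment[[seg]]
    if (!length(evs)) return(NULL)
    starts <- vapply(evs, `[[`, numeric(1), "start_s")
    dirs <- vapply(evs, `[[`, numeric(1), "direction")
    ok <- !used[[seg]] & abs(starts - ref$start_s) <= max_onset_gap &
      dirs == ref$direction
    if (!any(ok)) return(NULL)
    i <- which(ok)[which.min(abs(starts[ok] - ref$start_s))]
    used[[seg]][i] <<- TRUE
    evs[[i]]
  }
  triples <- list()
  n_drop <- 0L
  for (h in head_ev) {
    st <- pick("sternum", h)
    pv <- pick("pelvis", h)
    if (is.null(st) || is.null(pv)) { n_drop <- n_drop + 1L; next }
    triples[[length(triples) + 1L]] <- list(head = h, sternum = st, pelvis = pv)
  }
  if (n_drop > 0L)
    message("match_turns: dropped ", n_drop,
            " turn(s) without a match in all three segments")
  triples
}

#' Intersegmental turning onset latency
#'
#' Start-time difference of a matched segment pair, referenced to the more
#' cranial segment: `start(cranial) - start(caudal)`. A negative value means
#' the cranial segment started turning first (the healthy top-down
#' sequence); values near zero indicate en bloc turning.
#'
#' @param cranial,caudal matched [turn_event]s of the pair.
#' @return latency in seconds (signed).
#' @export
onset_latency <- function(cranial, caudal) {
  cranial$start_s - caudal$start_s
}

#' Maximum intersegmental angle over a turn
#'
#' Maximum absolute difference between two segments' yaw signals inside the
#' turn window, after re-referencing each signal to its pre-turn plateau
#' mean (a 0.5 s window ending 0.1 s before the window start) so that
#' static posture offsets between the segments cancel. Small values indicate
#' en bloc turning.
#'
#' @param yaw_cranial,yaw_caudal [segment_yaw_signal]s on a common time base.
#' @param window numeric `c(start_s, end_s)` — the union of the pair's turn
#'   windows.
#' @param reref_window `c(length, gap)` of the pre-turn reference window in
#'   seconds.
#' @param filter_cutoff_hz optional low-pass cutoff applied to both yaw
#'   signals before differencing (the pipeline passes its yaw filter
#'   cutoff); `NULL` uses the signals as given.
#' @return maximum intersegmental angle in degrees (>= 0).
#' @export
max_intersegmental_angle <- function(yaw_cranial, yaw_caudal, window,
                                     reref_window = c(0.5, 0.1),
                                     filter_cutoff_hz = NULL) {
  stopifnot(length(window) == 2L)
  if (!(window[2] > window[1])) stop("empty turn window")
  fs <- yaw_cranial$fs
  stopifnot(fs == yaw_caudal$fs,
            length(yaw_cranial$yaw_deg) == length(yaw_caudal$yaw_deg))
  y_cr <- yaw_cranial$yaw_deg
  y_ca <- yaw_caudal$yaw_deg
  if (!is.null(filter_cutoff_hz)) {
    y_cr <- lowpass_signal(y_cr, fs, filter_cutoff_hz)
    y_ca <- lowpass_signal(y_ca, fs, filter_cutoff_hz)
  }
  tt <- (seq_along(y_cr) - 1L) / fs
  ref_sel <- tt >= window[1] - reref_window[1] - reref_window[2] &
    tt <= window[1] - reref_window[2]
  win_sel <- tt >= window[1] & tt <= window[2]
  if (!any(win_sel)) stop("turn window contains no samples")
  ref_of <- function(y) if (any(ref_sel) && any(!is.na(y[ref_sel])))
    mean(y[ref_sel], na.rm = TRUE) else 0
  d <- (y_cr - ref_of(y_cr)) - (y_ca - ref_of(y_ca))
  max(abs(d[win_sel]), na.rm = TRUE)
}

#' Per-turn measures for one matched turn triple
#'
#' Turn duration and the step-count window use the pelvis turn (the most
#' whole-body-representative segment); peak angular velocity uses each
#' segment's own window; latencies and maximum intersegmental angles are
#' computed for the three cranial-caudal pairs.
#'
#' @param triple one element of [match_turns()] output.
#' @param yaw named list of the three [segment_yaw_signal]s.
#' @param contacts gait-event data.frame from [trial_contacts()].
#' @param filter_cutoff_hz yaw smoothing for the intersegmental angles.
#' @return one-row data.frame of per-turn measures.
#' @export
turn_measures <- function(triple, yaw, contacts, filter_cutoff_hz = 6) {
  pel <- triple$pelvis
  out <- data.frame(duration_s = pel$end_s - pel$start_s,
                    n_steps = steps_in_window(contacts,
                                              c(pel$start_s, pel$end_s)))
  for (s in names(triple)) {
    out[[paste0("peak_omega_", s)]] <- triple[[s]]$peak_omega_degps
    out[[paste0("magnitude_", s)]] <- triple[[s]]$magnitude_deg
  }
  for (p in .PAIRS) {
    cr <- triple[[p[2]]]; ca <- triple[[p[1]]]   # p = (caudal, cranial)
    out[[paste0("latency_", pair_name(p))]] <- onset_latency(cr, ca)
    win <- c(min(cr$start_s, ca$start_s), max(cr$end_s, ca$end_s))
    out[[paste0("max_angle_", pair_name(p))]] <-
      max_intersegmental_angle(yaw[[p[2]]], yaw[[p[1]]], win,
                               filter_cutoff_hz = filter_cutoff_hz)
  }
  out
}

#' Average per-turn measures into trial-level metrics
#'
#' Arithmetic mean of every measure over the matched turns (latencies are
#' averaged signed, matching the convention that negative group means
#' indicate a preserved top-down sequence).
#'
#' @param measures data.frame of per-turn measures ([turn_measures()] rows).
#' @param gait_speed straight-walking gait speed in m/s.
#' @param subject_id,group,condition trial identifiers.
#' @return one-row data.frame of class `trial_metrics`.
#' @export
aggregate_trial <- function(measures, gait_speed, subject_id, group,
                            condition) {
  if (is.null(measures) || !nrow(measures))
    stop("invalid trial: no matched turns to aggregate")
  out <- data.frame(subject_id = subject_id, group = group,
                    condition = condition,
                    n_turns_used = nrow(measures),
                    gait_speed_mps = gait_speed)
  for (cc in names(measures)) out[[cc]] <- mean(measures[[cc]])
  class(out) <- c("trial_metrics", class(out))
  out
}

#' Run the full turn analysis on one trial
#'
#' Marker clusters to segment yaw, yaw rates, per-segment turn detection,
#' cross-segment matching, gait events, gait speed, per-turn measures and
#' their trial-level averages.
#'
#' @param trial a [trial_record()].
#' @param filter_cutoff_hz yaw low-pass cutoff (Hz).
#' @param penalty change-point penalty (`NULL`: automatic).
#' @param min_turn_magnitude,plateau_omega_thresh,refine_frac see
#'   [detect_turns()].
#' @param max_onset_gap see [match_turns()].
#' @param contact_prominence,min_step_interval see [detect_contacts()].
#' @return object of class `trial_analysis`: fields `yaw`, `omega`, `turns`
#'   (per segment), `matched`, `contacts`, `gait_speed_mps`, `measures`
#'   (per matched turn) and `metrics` (one [aggregate_trial()] row, or
#'   `NULL` when no turn triple was found).
#' @export
analyze_trial <- function(trial, filter_cutoff_hz = 6, penalty = NULL,
                          min_turn_magnitude = 90, plateau_omega_thresh = 20,
                          refine_frac = 0.05, max_onset_gap = 1.5,
                          contact_prominence = 0.2, min_step_interval = 0.3) {
  segs <- c("head", "sternum", "pelvis")
  yaw <- lapply(stats::setNames(segs, segs), function(s)
    segment_yaw(segment_markers(trial, s), segment = s))
  omega <- lapply(yaw, angular_velocity, filter_cutoff_hz = filter_cutoff_hz)
  turns <- lapply(stats::setNames(segs, segs), function(s)
    detect_turns(yaw[[s]], omega[[s]], penalty = penalty,
                 min_turn_magnitude = min_turn_magnitude,
                 plateau_omega_thresh = plateau_omega_thresh,
                 refine_frac = refine_frac,
                 filter_cutoff_hz = filter_cutoff_hz))
  matched <- match_turns(turns, max_onset_gap = max_onset_gap)
  contacts <- trial_contacts(trial, min_prominence = contact_prominence,
                             min_step_interval = min_step_interval)
  speed <- gait_speed(segment_markers(trial, "pelvis"), turns$pelvis)
  measures <- if (length(matched))
    do.call(rbind, lapply(matched, turn_measures, yaw = yaw,
                          contacts = contacts,
                          filter_cutoff_hz = filter_cutoff_hz)) else NULL
  metrics <- if (!is.null(measures))
    aggregate_trial(measures, speed, trial$subject_id, trial$group,
                    trial$condition) else NULL
  structure(list(yaw = yaw, omega = omega, turns = turns, matched = matched,
                 contacts = contacts, gait_speed_mps = speed,
                 measures = measures, metrics = metrics),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("<trial_analysis> %d matched turns, gait speed %.2f m/s\n",
              length(x$matched), x$gait_speed_mps))
  if (!is.null(x$metrics))
    cat(sprintf("  mean turn: %.2f s, %.1f steps, %.0f deg (pelvis)\n",
                x$metrics$duration_s, x$metrics$n_steps,
                x$metrics$magnitude_pelvis))
  invisible(x)
}

#' Long-format cohort table
#'
#' Stacks trial metrics into the long layout consumed by the statistics
#' layer: one row per subject x condition x measure with columns
#' `subject_id, group, condition, gait_speed_mps, n_turns_used, measure,
#' value`.
#'
#' @param metrics_list list of [aggregate_trial()] rows (or a stacked wide
#'   data.frame of them).
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(metrics_list) {
  wide <- if (is.data.frame(metrics_list)) metrics_list
          else do.call(rbind, metrics_list)
  id_cols <- c("subject_id", "group", "condition", "n_turns_used",
               "gait_speed_mps")
  meas_cols <- setdiff(names(wide), id_cols)
  long <- do.call(rbind, lapply(meas_cols, function(mc)
    data.frame(wide[c("subject_id", "group", "condition", "gait_speed_mps",
                      "n_turns_used")],
               measure = mc, value = wide[[mc]])))
  long <- long[order(long$subject_id, long$condition, long$measure), ]
  rownames(long) <- NULL
  as_cohort_table(long)
}

#' Validate and tag a long-format cohort table
#' @param df data.frame in the [cohort_table()] layout.
#' @return the same data.frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  need <- c("subject_id", "group", "condition", "measure", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  g_per_subj <- tapply(df$group, df$subject_id,
                       function(g) length(unique(g)))
  if (any(g_per_subj > 1L))
    stop("each subject must belong to exactly one group")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}
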