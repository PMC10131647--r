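# Synthetic turning-while-walking trials with exact ground truth.
#
# Yaw transitions use a quintic smoothstep: C2-continuous, compact support,
# exact plateaus outside the transition and an analytic peak rate. The
# transition is parameterised by its 5-95% duration, like the descriptive
# turn durations used in gait labs.

# s(u) = 10u^3 - 15u^4 + 6u^5 on [0,1]; s(.U05) = 0.05 (solved once)
.U05 <- 0.189255377437770
.SPAN_5_95 <- 1 - 2 * .U05           # fraction of the support between 5-95%
.PEAK_RATE <- 1.875                  # s'(1/2)

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * u * (10 + u * (-15 + 6 * u))
}
smoothstep_rate <- function(u) {
  out <- numeric(length(u))
  inside <- u > 0 & u < 1
  ui <- u[inside]
  out[inside] <- 30 * ui^2 * (1 - ui)^2
  out
}

.SEGMENTS <- c("head", "sternum", "pelvis")

#' Simulation configuration
#'
#' Parameters of the synthetic walking-and-turning paradigm: a subject walks
#' up and down a walkway at self-selected speed for the trial duration,
#' executing 180 degree turns with a top-down head, sternum, pelvis onset
#' sequence. All defaults reflect the study paradigm (30 s trials at 200 Hz
#' on a 5 m walkway) and typical adult turning kinematics.
#'
#' @param n_turns number of turns in the trial.
#' @param turn_magnitude_deg nominal yaw change per turn (degrees).
#' @param turn_duration_s 5-95\% duration of each segment's yaw transition;
#'   a scalar or a named vector over `head`, `sternum`, `pelvis`.
#' @param onset_latency_s named vector of transition onset delays (s)
#'   relative to the head; `head` must be 0. Positive values give the
#'   healthy top-down sequence.
#' @param peak_angular_velocity_degps optional named vector; when given for a
#'   segment it overrides `turn_duration_s` via the analytic smoothstep
#'   relation (peak rate = 1.875 * magnitude / support duration).
#' @param step_frequency_hz cadence, steps per second (both feet pooled).
#' @param walking_speed_mps self-selected walking speed; the 0.8 m/s default
#'   is typical of mixed clinical cohorts on a turning-rich task and keeps
#'   the time-scheduled turning path of a default 30 s / 4-turn trial within
#'   the 5 m walkway.
#' @param walkway_length_m walkway length; exceeding it raises a warning.
#' @param trial_duration_s trial length in seconds.
#' @param marker_noise_sd_m Gaussian noise SD added to every marker
#'   coordinate (metres).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed; a fixed seed makes the trial bit-reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_turns = 4,
                              turn_magnitude_deg = 180,
                              turn_duration_s = 2.0,
                              onset_latency_s = c(head = 0, sternum = 0.08,
                                                  pelvis = 0.18),
                              peak_angular_velocity_degps = NULL,
                              step_frequency_hz = 1.8,
                              walking_speed_mps = 0.8,
                              walkway_length_m = 5,
                              trial_duration_s = 30,
                              marker_noise_sd_m = 0.002,
                              fs = 200,
                              seed = NULL) {
  dur <- expand_by_segment(turn_duration_s, "turn_duration_s")
  lat <- expand_by_segment(onset_latency_s, "onset_latency_s")
  if (abs(lat[["head"]]) > 0)
    stop("onset_latency_s['head'] must be 0 (head is the reference)")
  if (!is.null(peak_angular_velocity_degps)) {
    pk <- peak_angular_velocity_degps
    stopifnot(!is.null(names(pk)), all(names(pk) %in% .SEGMENTS), all(pk > 0))
    # peak = .PEAK_RATE * M / D and D = dur / .SPAN_5_95
    dur[names(pk)] <- .PEAK_RATE * turn_magnitude_deg * .SPAN_5_95 / pk
  }
  stopifnot(n_turns >= 1, turn_magnitude_deg > 0, all(dur > 0), fs > 0,
            trial_duration_s > 0, walking_speed_mps >= 0,
            step_frequency_hz > 0, marker_noise_sd_m >= 0)
  structure(list(
    n_turns = as.integer(n_turns),
    turn_magnitude_deg = turn_magnitude_deg,
    turn_duration_s = dur,
    onset_latency_s = lat,
    step_frequency_hz = step_frequency_hz,
    walking_speed_mps = walking_speed_mps,
    walkway_length_m = walkway_length_m,
    trial_duration_s = trial_duration_s,
    marker_noise_sd_m = marker_noise_sd_m,
    fs = fs, seed = seed), class = "simulation_config")
}

expand_by_segment <- function(x, what) {
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(x, 3), .SEGMENTS)
  if (is.null(names(x)) || !all(.SEGMENTS %in% names(x)))
    stop(what, " must be a scalar or named over head/sternum/pelvis")
  x[.SEGMENTS]
}

#' Analytic peak angular velocity implied by a configuration
#' @param cfg a [simulation_config()].
#' @return named vector of peak yaw rates (deg/s) per segment.
#' @export
config_peak_omega <- function(cfg) {
  D <- cfg$turn_duration_s / .SPAN_5_95
  .PEAK_RATE * cfg$turn_magnitude_deg / D
}

# anatomically plausible marker clusters, segment frame, metres
segment_triads <- function() {
  list(
    head = rbind(c(0.09, 0.00, 0.05), c(-0.07, 0.08, 0.00),
                 c(-0.07, -0.08, 0.00)),
    sternum = rbind(c(0.08, 0.00, 0.02), c(-0.06, 0.07, -0.04),
                    c(-0.06, -0.07, -0.04)),
    pelvis = rbind(c(0.00, 0.12, 0.00), c(0.00, -0.12, 0.00),
                   c(-0.13, 0.00, 0.03)))
}
segment_heights <- c(head = 1.65, sternum = 1.35, pelvis = 1.00)

#' Simulate one walking-and-turning trial
#'
#' Builds noise-free segment yaw staircases (plateaus at 0 and +/- the turn
#' magnitude, alternating direction, joined by smoothstep transitions whose
#' onsets honour the configured top-down latencies), rotates rigid marker
#' triads accordingly, translates them along the walking path, attaches
#' heel/toe markers whose vertical-velocity extrema sit exactly at the
#' scheduled foot contacts, and finally adds Gaussian marker noise.
#'
#' @param cfg a [simulation_config()].
#' @param subject_id,group,condition metadata for the emitted trial.
#' @return a list with elements `trial` (a [trial_record()]) and `truth`
#'   (class `ground_truth`: per-segment turn tables with both the full
#'   transition support (`start_s`, `end_s`) and the 5-95\%-of-magnitude
#'   boundaries (`start_5_s`, `end_95_s`) the detector reports, contact
#'   events, speed, and the configuration used).
#' @export
simulate_trial <- function(cfg, subject_id = "sim01", group = "young",
                           condition = "ST") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(cfg$seed)
  }
  fs <- cfg$fs
  T_n <- as.integer(round(cfg$trial_duration_s * fs))
  tt <- (seq_len(T_n) - 1L) / fs
  M <- cfg$turn_magnitude_deg
  D <- cfg$turn_duration_s / .SPAN_5_95          # full support durations
  lat <- cfg$onset_latency_s

  centers <- seq_len(cfg$n_turns) * cfg$trial_duration_s / (cfg$n_turns + 1)
  dir <- rep_len(c(1, -1), cfg$n_turns)
  # per-segment support intervals; validate no overlap / clipping
  seg_tab <- do.call(rbind, lapply(.SEGMENTS, function(s) {
    start <- centers - D[[s]] / 2 + lat[[s]]
    data.frame(segment = s, turn = seq_along(centers), start_s = start,
               end_s = start + D[[s]], magnitude_deg = M, direction = dir,
               peak_omega_degps = .PEAK_RATE * M / D[[s]],
               duration_5_95_s = cfg$turn_duration_s[[s]],
               # boundaries in the 5%/95%-of-magnitude convention that the
               # turn detector reports
               start_5_s = start + .U05 * D[[s]],
               end_95_s = start + (1 - .U05) * D[[s]],
               stringsAsFactors = FALSE)
  }))
  for (s in .SEGMENTS) {
    st <- seg_tab[seg_tab$segment == s, ]
    if (any(st$start_s < 0) || any(st$end_s > cfg$trial_duration_s))
      stop("turn transitions do not fit in the trial; shorten durations or latencies")
    if (cfg$n_turns > 1 && any(diff(st$start_s) < D[[s]]))
      stop("turns overlap: spacing is smaller than turn duration + latency")
  }

  yaw_nominal <- function(s) {
    st <- seg_tab[seg_tab$segment == s, ]
    y <- numeric(T_n)
    for (j in seq_len(nrow(st)))
      y <- y + st$direction[j] * M * smoothstep((tt - st$start_s[j]) / D[[s]])
    y
  }
  yaw <- lapply(stats::setNames(.SEGMENTS, .SEGMENTS), yaw_nominal)

  # walking path: forward at configured speed along the current pelvis heading
  phi <- yaw$pelvis * pi / 180
  dt <- 1 / fs
  px <- cumsum(cfg$walking_speed_mps * cos(phi) * dt)
  py <- cumsum(cfg$walking_speed_mps * sin(phi) * dt)
  if (diff(range(px)) > cfg$walkway_length_m)
    warning(sprintf("walking path spans %.2f m, exceeding the %g m walkway",
                    diff(range(px)), cfg$walkway_length_m))

  markers <- list()
  triads <- segment_triads()
  for (s in .SEGMENTS) {
    a <- yaw[[s]] * pi / 180
    ca <- cos(a); sa <- sin(a)
    local <- triads[[s]]
    for (i in 1:3) {
      lx <- local[i, 1]; ly <- local[i, 2]; lz <- local[i, 3]
      pos <- cbind(x = px + ca * lx - sa * ly,
                   y = py + sa * lx + ca * ly,
                   z = segment_heights[[s]] + lz)
      markers[[paste0(s, "_", i)]] <- pos
    }
  }

  con <- foot_contacts(cfg)
  for (side in c("l", "r")) {
    ic <- con$time_s[con$foot == side & con$kind == "initial_contact"]
    fc <- con$time_s[con$foot == side & con$kind == "final_contact"]
    zt <- foot_height(tt, lift_centers = fc, land_centers = ic,
                      amp = 0.8, width = 0.05)
    zh <- foot_height(tt, lift_centers = fc, land_centers = ic - 0.08,
                      amp = 0.6, width = 0.05)
    sgn <- if (side == "l") 1 else -1
    lat_off <- 0.10 * sgn
    fx_t <- 0.12; fx_h <- -0.08
    markers[[paste0("toe_", side)]] <- cbind(
      x = px + cos(phi) * fx_t - sin(phi) * lat_off,
      y = py + sin(phi) * fx_t + cos(phi) * lat_off,
      z = 0.02 + zt)
    markers[[paste0("heel_", side)]] <- cbind(
      x = px + cos(phi) * fx_h - sin(phi) * lat_off,
      y = py + sin(phi) * fx_h + cos(phi) * lat_off,
      z = 0.03 + zh)
  }

  if (cfg$marker_noise_sd_m > 0)
    markers <- lapply(markers, function(p)
      p + matrix(stats::rnorm(length(p), 0, cfg$marker_noise_sd_m), nrow(p)))

  trajs <- Map(function(lab, pos) marker_trajectory(lab, pos, fs = fs),
               names(markers), markers)
  trial <- trial_record(subject_id, group, condition, trajs)
  truth <- structure(list(segments = seg_tab, contacts = con,
                          speed_mps = cfg$walking_speed_mps, config = cfg),
                     class = "ground_truth")
  list(trial = trial, truth = truth)
}

# contact schedule: per-foot stride = 2 / cadence, 60% stance
foot_contacts <- function(cfg) {
  t_str <- 2 / cfg$step_frequency_hz
  stance <- 0.6 * t_str
  tmax <- cfg$trial_duration_s - 0.5
  out <- list()
  for (side in c("l", "r")) {
    t0 <- if (side == "l") 0.5 else 0.5 + t_str / 2
    ic <- seq(t0, tmax, by = t_str)
    fc <- ic + stance
    fc <- fc[fc <= tmax]
    out[[side]] <- rbind(
      data.frame(foot = side, kind = "initial_contact", time_s = ic),
      data.frame(foot = side, kind = "final_contact", time_s = fc))
  }
  con <- do.call(rbind, out)
  con <- con[order(con$time_s), ]
  rownames(con) <- NULL
  con
}

# vertical position as the analytic integral of Gaussian velocity bumps:
# a positive bump at each lift (toe-off) and a negative one at each landing,
# so velocity extrema sit exactly at the scheduled events.
foot_height <- function(tt, lift_centers, land_centers, amp, width) {
  z <- numeric(length(tt))
  for (c0 in lift_centers) z <- z + stats::pnorm((tt - c0) / width)
  for (c0 in land_centers) z <- z - stats::pnorm((tt - c0) / width)
  z <- amp * width * sqrt(2 * pi) * z
  z - min(z)               # stance level at zero, swing raised above it
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d turns x 3 segments, %d contacts, speed %.2f m/s\n",
              nrow(x$segments) / 3L, nrow(x$contacts), x$speed_mps))
  invisible(x)
}

#' Simulate a multi-group, multi-condition cohort
#'
#' Layers per-subject lognormal multipliers (turn duration, latencies and
#' walking speed) over group-level configurations and condition-level effect
#' shifts, and generates ST/SDT/CDT trials for every subject. Fully
#' reproducible under a fixed seed.
#'
#' @param design either a single [simulation_config()] used for all groups,
#'   or a named list mapping group name to a configuration.
#' @param n_subjects subjects per group: a scalar or named vector.
#' @param effects named list mapping condition (`"SDT"`, `"CDT"`) to a list
#'   of multipliers applied to that condition's trials:
#'   `latency_scale`, `duration_scale`, `speed_scale`, `cadence_scale`.
#'   Conditions absent from the list (always `"ST"`) are unmodified.
#' @param subject_sdlog SD (log scale) of the per-subject lognormal
#'   multipliers.
#' @param seed master seed for the cohort.
#' @return list of entries, each with `subject_id`, `group`, `condition`,
#'   `trial`, `truth`.
#' @export
simulate_cohort <- function(design, n_subjects, effects = list(),
                            subject_sdlog = 0.1, seed = 1) {
  if (inherits(design, "simulation_config")) {
    if (is.null(names(n_subjects)))
      stop("with a single config, n_subjects must be named by group")
    design <- stats::setNames(rep(list(design), length(n_subjects)),
                              names(n_subjects))
  }
  groups <- names(design)
  if (length(n_subjects) == 1L && is.null(names(n_subjects)))
    n_subjects <- stats::setNames(rep(n_subjects, length(groups)), groups)
  stopifnot(all(groups %in% names(n_subjects)))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  out <- list()
  for (g in groups) {
    base_cfg <- design[[g]]
    for (i in seq_len(n_subjects[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      mult <- exp(stats::rnorm(3, 0, subject_sdlog))  # duration, latency, speed
      for (cond in .conditions) {
        cfg <- base_cfg
        cfg$turn_duration_s <- cfg$turn_duration_s * mult[1]
        cfg$onset_latency_s[c("sternum", "pelvis")] <-
          cfg$onset_latency_s[c("sternum", "pelvis")] * mult[2]
        cfg$walking_speed_mps <- cfg$walking_speed_mps * mult[3]
        ef <- effects[[cond]]
        if (!is.null(ef)) {
          if (!is.null(ef$latency_scale))
            cfg$onset_latency_s[c("sternum", "pelvis")] <-
              cfg$onset_latency_s[c("sternum", "pelvis")] * ef$latency_scale
          if (!is.null(ef$duration_scale))
            cfg$turn_duration_s <- cfg$turn_duration_s * ef$duration_scale
          if (!is.null(ef$speed_scale))
            cfg$walking_speed_mps <- cfg$walking_speed_mps * ef$speed_scale
          if (!is.null(ef$cadence_scale))
            cfg$step_frequency_hz <- cfg$step_frequency_hz * ef$cadence_scale
        }
        cfg$seed <- sample.int(.Machine$integer.max, 1L)
        out[[length(out) + 1L]] <- c(
          list(subject_id = sid, group = g, condition = cond),
          simulate_trial(cfg, subject_id = sid, group = g, condition = cond))
      }
    }
  }
  out
}
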