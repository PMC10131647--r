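fake_event <- function(segment, start, dur = 2, dir = 1)
  turn_event(segment, start, start + dur, 160, dir, 100)

test_that("matching pairs turns across segments and drops incomplete ones", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  an <- quiet_analyze(sim$trial)
  expect_length(an$matched, 2L)
  for (tr in an$matched)
    expect_setequal(names(tr), c("head", "sternum", "pelvis"))

  # a segment missing one turn excludes that turn from every average
  ev <- list(head = list(fake_event("head", 5), fake_event("head", 12)),
             sternum = list(fake_event("sternum", 5.1)),
             pelvis = list(fake_event("pelvis", 5.2),
                           fake_event("pelvis", 12.2)))
  expect_message(m <- match_turns(ev), "dropped 1")
  expect_length(m, 1L)

  # turns 10 s apart are never cross-matched
  ev2 <- list(head = list(fake_event("head", 5)),
              sternum = list(fake_event("sternum", 15)),
              pelvis = list(fake_event("pelvis", 15)))
  expect_message(m2 <- match_turns(ev2), "dropped 1")
  expect_length(m2, 0L)

  # opposite directions never match
  ev3 <- list(head = list(fake_event("head", 5, dir = 1)),
              sternum = list(fake_event("sternum", 5.1, dir = -1)),
              pelvis = list(fake_event("pelvis", 5.2, dir = 1)))
  expect_message(m3 <- match_turns(ev3), "dropped 1")
  expect_length(m3, 0L)
})

test_that("onset latency honours the cranial-reference sign convention", {
  head <- fake_event("head", 1.00)
  pelvis <- fake_event("pelvis", 1.15)
  expect_equal(onset_latency(head, pelvis), -0.15)
  expect_equal(onset_latency(head, fake_event("pelvis", 1.00)), 0)
  # antisymmetry under role swap
  expect_equal(onset_latency(head, pelvis), -onset_latency(pelvis, head))
})

test_that("latency additivity holds exactly per matched turn", {
  an <- quiet_analyze(quick_trial(seed = 4)$trial)   # noisy trial
  md <- an$measures
  expect_equal(md$latency_pelvis_head,
               md$latency_sternum_head + md$latency_pelvis_sternum,
               tolerance = 1e-12)
})

test_that("max intersegmental angle: identity, offsets, delayed transitions", {
  fs <- 200
  tt <- (0:4000) / fs
  mk_yaw <- function(y, seg) structure(list(segment = seg, yaw_deg = y, fs = fs),
                                       class = "segment_yaw_signal")
  step <- function(delay) 180 * turnkin:::smoothstep((tt - 8 - delay) / 3.2)
  a <- mk_yaw(step(0), "head")
  expect_equal(max_intersegmental_angle(a, a, c(8, 11.2)), 0)
  # common constant offsets cancel (and so do static posture offsets)
  b <- mk_yaw(step(0) + 7, "sternum")
  expect_equal(max_intersegmental_angle(a, b, c(8, 11.2)), 0, tolerance = 1e-9)

  # delayed copy: the analytic maximum of the shifted-smoothstep difference
  for (d in c(0.1, 0.3)) {
    del <- mk_yaw(step(d), "pelvis")
    u <- seq(0, 1 + d / 3.2, by = 1e-4)
    analytic <- 180 * max(turnkin:::smoothstep(u) -
                            turnkin:::smoothstep(u - d / 3.2))
    got <- max_intersegmental_angle(a, del, c(8, 11.2 + d))
    expect_equal(got, analytic, tolerance = 0.02 * analytic)
  }
  expect_error(max_intersegmental_angle(a, a, c(9, 9)), "empty")
})

test_that("en bloc trials give near-zero latencies and intersegmental angles", {
  sim <- quick_trial(onset_latency_s = c(head = 0, sternum = 0, pelvis = 0),
                     seed = 9)                     # default 2 mm noise
  an <- quiet_analyze(sim$trial)
  expect_lt(abs(an$metrics$latency_pelvis_head), 0.02)
  expect_lt(an$metrics$max_angle_pelvis_head, 1)
  expect_lt(an$metrics$max_angle_sternum_head, 1)
})

test_that("trial aggregation averages per-turn measures", {
  m <- data.frame(duration_s = c(2.0, 2.2, 2.4), n_steps = c(3, 4, 5))
  out <- aggregate_trial(m, gait_speed = 1.1, "s1", "pd", "ST")
  expect_equal(out$duration_s, 2.2)
  expect_equal(out$n_steps, 4)
  expect_equal(out$n_turns_used, 3L)
  single <- aggregate_trial(m[2, ], 1.1, "s1", "pd", "ST")
  expect_equal(single$duration_s, 2.2)
  expect_error(aggregate_trial(m[0, ], 1.1, "s1", "pd", "ST"), "invalid trial")
})

test_that("cohort means reproduce the configured top-down ordering", {
  coh <- simulate_cohort(quick_cfg(), n_subjects = c(young = 5), seed = 21)
  st_trials <- Filter(function(e) e$condition == "ST", coh)
  rows <- lapply(st_trials, function(e) quiet_analyze(e$trial)$metrics)
  tab <- do.call(rbind, rows)
  expect_lt(mean(tab$latency_pelvis_head), mean(tab$latency_sternum_head))
  expect_lt(mean(tab$latency_sternum_head), 0)
})

test_that("cohort tables enforce one group per subject", {
  df <- data.frame(subject_id = c("a", "a"), group = c("pd", "lbp"),
                   condition = c("ST", "SDT"), measure = "m", value = 1)
  expect_error(as_cohort_table(df), "exactly one group")
})
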