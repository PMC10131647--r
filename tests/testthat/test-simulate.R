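test_that("fixed seed makes trials bit-reproducible", {
  a <- quick_trial(seed = 7)
  b <- quick_trial(seed = 7)
  expect_identical(a$trial$markers, b$trial$markers)
  expect_identical(a$truth$segments, b$truth$segments)
  c <- quick_trial(seed = 8)
  expect_false(identical(a$trial$markers, c$trial$markers))
})

test_that("ground truth encodes the configured turn structure exactly", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  gt <- sim$truth$segments
  expect_equal(nrow(gt), 2 * 3)                  # 2 turns x 3 segments
  hd <- gt[gt$segment == "head", ]
  pv <- gt[gt$segment == "pelvis", ]
  st <- gt[gt$segment == "sternum", ]
  # top-down: head onsets strictly before sternum before pelvis
  expect_true(all(hd$start_s < st$start_s))
  expect_true(all(st$start_s < pv$start_s))
  # configured latency is honoured exactly
  expect_equal(pv$start_s - hd$start_s, rep(0.18, 2))
  expect_equal(st$start_s - hd$start_s, rep(0.08, 2))
  expect_true(all(gt$start_s < gt$end_s))
  # alternating direction
  expect_equal(hd$direction, c(1, -1))
})

test_that("noise-free yaw sits exactly on the configured plateaus", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  yaw <- segment_yaw(segment_markers(sim$trial, "head"))
  gt <- sim$truth$segments
  hd <- gt[gt$segment == "head", ]
  fs <- trial_fs(sim$trial)
  at <- function(t) yaw$yaw_deg[round(t * fs) + 1L]
  # mid-plateau samples: before the first, between, and after the last turn
  expect_equal(at(hd$start_s[1] / 2), 0, tolerance = 1e-9)
  expect_equal(at((hd$end_s[1] + hd$start_s[2]) / 2), 180, tolerance = 1e-9)
  expect_equal(at((hd$end_s[2] + sim$truth$config$trial_duration_s) / 2), 0,
               tolerance = 1e-9)
})

test_that("the analytic peak angular velocity is attained", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  for (s in c("head", "pelvis")) {
    yaw <- segment_yaw(segment_markers(sim$trial, s))
    # raw numerical derivative of the noise-free yaw, no filtering involved
    omega_num <- max(abs(diff(yaw$yaw_deg))) * yaw$fs
    expect_equal(omega_num, unname(config_peak_omega(sim$truth$config)[s]),
                 tolerance = 0.01)
  }
})

test_that("peak-velocity parameterisation inverts the duration relation", {
  cfg <- simulation_config(
    peak_angular_velocity_degps = c(head = 150, sternum = 120, pelvis = 100))
  expect_equal(unname(config_peak_omega(cfg)), c(150, 120, 100),
               tolerance = 1e-12)
})

test_that("impossible configurations are rejected", {
  # turns longer than their spacing must overlap
  expect_error(simulate_trial(simulation_config(n_turns = 4,
                                                trial_duration_s = 12)),
               "overlap|do not fit")
  expect_error(simulation_config(onset_latency_s = c(head = 0.1, sternum = 0,
                                                     pelvis = 0)),
               "head")
  expect_error(simulation_config(turn_duration_s = -1))
})

test_that("cohort generation is reproducible and covers the design", {
  coh <- simulate_cohort(quick_cfg(), n_subjects = c(pd = 3, lbp = 3),
                         seed = 11)
  expect_length(coh, 2 * 3 * 3)                  # groups x subjects x conditions
  expect_setequal(unique(vapply(coh, `[[`, character(1), "condition")),
                  c("ST", "SDT", "CDT"))
  coh2 <- simulate_cohort(quick_cfg(), n_subjects = c(pd = 3, lbp = 3),
                          seed = 11)
  expect_identical(coh[[5]]$trial$markers, coh2[[5]]$trial$markers)
})

test_that("condition effects shift ground-truth parameters as configured", {
  effects <- list(CDT = list(latency_scale = 0.3, duration_scale = 1.3))
  coh <- simulate_cohort(quick_cfg(), n_subjects = c(young = 6),
                         effects = effects, seed = 5)
  lat_of <- function(e) {
    gt <- e$truth$segments
    gt$start_s[gt$segment == "pelvis"][1] - gt$start_s[gt$segment == "head"][1]
  }
  conds <- vapply(coh, `[[`, character(1), "condition")
  lat <- vapply(coh, lat_of, numeric(1))
  expect_lt(mean(lat[conds == "CDT"]), mean(lat[conds == "ST"]))
  # with no effects, per-condition ground-truth means agree exactly
  # (conditions share each subject's multipliers)
  coh0 <- simulate_cohort(quick_cfg(), n_subjects = c(young = 6), seed = 5)
  lat0 <- vapply(coh0, lat_of, numeric(1))
  conds0 <- vapply(coh0, `[[`, character(1), "condition")
  expect_equal(mean(lat0[conds0 == "CDT"]), mean(lat0[conds0 == "ST"]),
               tolerance = 1e-12)
})
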