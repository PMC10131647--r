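test_that("yaw of an analytically rotated cluster is recovered", {
  cl <- oracle_cluster()
  Tn <- 100
  # ramp 0 -> 90 degrees about z
  rots <- lapply(seq(0, 90, length.out = Tn), rot_z)
  yaw <- segment_yaw(cluster_trajectories(cl, rots), segment = "head")
  expect_equal(yaw$yaw_deg[1], 0, tolerance = 1e-9)
  expect_equal(yaw$yaw_deg[Tn], 90, tolerance = 1e-6)
  expect_true(all(diff(yaw$yaw_deg) > 0))

  # pure translation: yaw identically zero
  off <- cbind(seq_len(Tn) / 50, -seq_len(Tn) / 80, seq_len(Tn) / 100)
  rots_id <- rep(list(diag(3)), Tn)
  yaw_t <- segment_yaw(cluster_trajectories(cl, rots_id, off), segment = "head")
  expect_equal(yaw_t$yaw_deg, rep(0, Tn), tolerance = 1e-9)
})

test_that("continuous rotation through 180 degrees stays unwrapped", {
  cl <- oracle_cluster()
  angles <- seq(160, 200, length.out = 50)
  yaw <- segment_yaw(cluster_trajectories(cl, lapply(angles, rot_z)),
                     segment = "head")
  # reported relative to the first frame (160): ends at +40, not -320
  expect_equal(yaw$yaw_deg[50] - yaw$yaw_deg[1], 40, tolerance = 1e-6)
  expect_true(all(abs(diff(yaw$yaw_deg)) < 180))
  # and the raw unwrapping utility honours the 170 -> 190 contract
  expect_equal(unwrap_deg(c(170, 179, -172, -165))[3], 188)
})

test_that("yaw matches the Euler z-angle of composed rotations", {
  cl <- oracle_cluster()
  # 10 degrees about x, then 37 about z: yaw must read 37
  R <- rot_z(37) %*% rot_x(10)
  yaw <- segment_yaw(cluster_trajectories(cl, list(diag(3), R, R)),
                     segment = "head")
  expect_equal(yaw$yaw_deg[2], 37, tolerance = 1e-6)

  # random z-y-x rotations: yaw recovered to < 1e-6 degrees
  set.seed(31)
  for (i in 1:25) {
    psi <- runif(1, -179, 179)
    R <- rot_z(psi) %*% rot_y(runif(1, -20, 20)) %*% rot_x(runif(1, -20, 20))
    expected <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    yaw <- segment_yaw(cluster_trajectories(cl, list(diag(3), R)),
                       segment = "head")
    expect_equal(yaw$yaw_deg[2], expected, tolerance = 1e-6)
  }
})

test_that("yaw is translation-invariant and z-rotation-equivariant", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  mk <- segment_markers(sim$trial, "sternum")
  base <- segment_yaw(mk, segment = "sternum")$yaw_deg
  ref <- t(vapply(mk, function(m) m$positions[1, ], numeric(3)))
  shift <- c(3.2, -1.5, 0.4)
  mk_t <- lapply(mk, function(m) {
    m$positions <- sweep(m$positions, 2, -shift)
    m
  })
  expect_equal(segment_yaw(mk_t, segment = "sternum")$yaw_deg, base,
               tolerance = 1e-9)
  # rotating the whole marker set about z, against the unrotated reference
  # configuration, adds exactly that angle to the yaw
  alpha <- 25
  Rz <- rot_z(alpha)
  mk_r <- lapply(mk, function(m) {
    m$positions <- m$positions %*% t(Rz)
    m
  })
  expect_equal(segment_yaw(mk_r, segment = "sternum",
                           reference = ref)$yaw_deg, base + alpha,
               tolerance = 1e-9)
})

test_that("degenerate clusters are rejected", {
  Tn <- 10
  collinear <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0))
  expect_error(segment_yaw(cluster_trajectories(collinear,
                                                rep(list(diag(3)), Tn))),
               "collinear")
})

test_that("angular velocity recovers ramps, constants and transitions", {
  fs <- 200
  tt <- (0:2000) / fs
  ramp <- structure(list(segment = "head", yaw_deg = 60 * tt, fs = fs),
                    class = "segment_yaw_signal")
  om <- angular_velocity(ramp)
  core <- 100:1900
  expect_equal(om$omega_degps[core], rep(60, length(core)), tolerance = 1e-5)

  flat <- ramp; flat$yaw_deg <- rep(42, length(tt))
  expect_equal(angular_velocity(flat)$omega_degps, rep(0, length(tt)),
               tolerance = 1e-7)

  # smoothstep transition: peak rate matches the analytic derivative
  sim <- quick_trial(marker_noise_sd_m = 0)
  yaw <- segment_yaw(segment_markers(sim$trial, "head"))
  om2 <- angular_velocity(yaw)
  expect_equal(max(abs(om2$omega_degps)),
               unname(config_peak_omega(sim$truth$config)["head"]),
               tolerance = 0.02)

  expect_error(angular_velocity(ramp, filter_cutoff_hz = 120), "Nyquist")
})

test_that("time reversal negates and reverses the angular velocity", {
  sim <- quick_trial(marker_noise_sd_m = 0)
  yaw <- segment_yaw(segment_markers(sim$trial, "pelvis"))
  fwd <- angular_velocity(yaw)$omega_degps
  yaw_rev <- yaw; yaw_rev$yaw_deg <- rev(yaw$yaw_deg)
  bwd <- angular_velocity(yaw_rev)$omega_degps
  core <- 50:(length(fwd) - 50)
  expect_equal(bwd[core], -rev(fwd)[core], tolerance = 1e-6)
})

test_that("gait speed averages straight-walking intervals only", {
  fs <- 200; Tn <- 1000
  mk <- lapply(1:3, function(i)
    marker_trajectory(paste0("pelvis_", i),
                      cbind(x = 1.2 * (1:Tn) / fs + i / 10, y = i / 20, z = 1),
                      fs = fs))
  expect_equal(gait_speed(mk), 1.2, tolerance = 1e-3)

  still <- lapply(mk, function(m) { m$positions[, "x"] <- 0.5; m })
  expect_equal(gait_speed(still), 0, tolerance = 1e-6)

  # simulated trial at a configured 1.0 m/s, recovered within 5%
  sim <- quick_trial(walking_speed_mps = 1.0, walkway_length_m = 7,
                     marker_noise_sd_m = 0)
  an <- quiet_analyze(sim$trial)
  expect_equal(an$gait_speed_mps, 1.0, tolerance = 0.05)

  # a turn spanning everything leaves no straight interval
  ev <- list(turn_event("pelvis", 0, Tn / fs, 180, 1, 100))
  expect_error(gait_speed(mk, ev), "no straight-walking")
})

test_that("short occlusion gaps are bridged, long gaps stay invalid", {
  m <- marker_trajectory("a", cbind(x = 1:100 / 100, y = 0, z = 1), fs = 200)
  m$positions[20:25, ] <- NA        # 6-sample gap: bridged
  m$positions[60:80, ] <- NA        # 21-sample gap: kept
  out <- interpolate_gaps(m, max_gap = 10L)
  expect_false(anyNA(out$positions[20:25, ]))
  expect_equal(out$positions[20:25, "x"], 20:25 / 100, tolerance = 1e-12)
  expect_true(all(is.na(out$positions[60:80, ])))
})
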