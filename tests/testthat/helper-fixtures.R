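# Shared fixtures: small, fast trial configurations and oracle helpers.

# short 2-turn trial that fits the walkway at the default speed
quick_cfg <- function(n_turns = 2, trial_duration_s = 15, seed = 1, ...) {
  simulation_config(n_turns = n_turns, trial_duration_s = trial_duration_s,
                    seed = seed, ...)
}

quick_trial <- function(...) {
  suppressWarnings(simulate_trial(quick_cfg(...)))
}

quiet_analyze <- function(trial, ...) {
  suppressMessages(suppressWarnings(analyze_trial(trial, ...)))
}

# rotation matrices for analytic kinematics oracles
rot_x <- function(a) {
  a <- a * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}
rot_y <- function(a) {
  a <- a * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}
rot_z <- function(a) {
  a <- a * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# a non-collinear 4-marker cluster used by the kinematics oracles
oracle_cluster <- function() {
  rbind(c(0.10, 0.00, 0.02), c(-0.05, 0.08, 0.00),
        c(-0.05, -0.08, 0.01), c(0.00, 0.02, 0.09))
}

# build marker trajectories for a cluster under a per-frame rotation +
# translation: rotations is a list of 3x3 matrices (length T), offsets T x 3
cluster_trajectories <- function(cluster, rotations, offsets = NULL, fs = 200) {
  Tn <- length(rotations)
  if (is.null(offsets)) offsets <- matrix(0, Tn, 3)
  lapply(seq_len(nrow(cluster)), function(i) {
    pos <- t(vapply(seq_len(Tn),
                    function(t) rotations[[t]] %*% cluster[i, ] + offsets[t, ],
                    numeric(3)))
    marker_trajectory(paste0("m_", i), pos, fs = fs)
  })
}

# exhaustive single-split oracle
exhaustive_split <- function(x) {
  n <- length(x)
  costs <- vapply(1:(n - 1), function(k) {
    a <- x[1:k]; b <- x[(k + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  list(index = which.min(costs), cost = min(costs))
}

# brute-force optimal segmentation (dynamic programming) oracle:
# minimises total RSS + penalty per change point
dp_segmentation <- function(x, penalty) {
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  rss <- function(i, j) {
    m <- (s1[j + 1] - s1[i]) / (j - i + 1)
    s2[j + 1] - s2[i] - (j - i + 1) * m^2
  }
  best <- c(0, rep(Inf, n)); prev <- integer(n + 1)
  for (j in 1:n) for (i in 1:j) {
    c0 <- best[i] + rss(i, j) + if (i > 1) penalty else 0
    if (c0 < best[j + 1] - 1e-12) { best[j + 1] <- c0; prev[j + 1] <- i }
  }
  cps <- integer(0); j <- n
  while (j > 0) { i <- prev[j + 1]; if (i > 1) cps <- c(i - 1L, cps); j <- i - 1 }
  cps
}

# random staircase with well-separated mean shifts (the regime the turning
# signals live in: plateau jumps of many tens of degrees over unit noise)
staircase_signal <- function(n, n_cp, jump_range = c(60, 180), noise_sd = 1,
                             min_seg = 5L) {
  repeat {
    cps <- sort(sample(min_seg:(n - min_seg), n_cp))
    if (n_cp < 2L || all(diff(cps) >= min_seg)) break
  }
  means <- cumsum(c(0, stats::runif(n_cp, jump_range[1], jump_range[2]) *
                      sample(c(-1, 1), n_cp, replace = TRUE)))
  seg <- findInterval(seq_len(n), cps + 1L) + 1L
  list(x = means[seg] + stats::rnorm(n, 0, noise_sd), cps = cps)
}

# long-format null cohort table (no group or condition effects)
null_cohort <- function(n_per = 8, groups = c("young", "older", "pd"),
                        sd_subject = 1, sd_noise = 1) {
  rows <- list()
  for (g in groups) for (i in seq_len(n_per)) {
    sid <- paste0(g, i)
    b <- stats::rnorm(1, 0, sd_subject)
    for (cc in c("ST", "SDT", "CDT"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = g, condition = cc,
        gait_speed_mps = stats::rnorm(1, 1, 0.1), n_turns_used = 4,
        measure = "m", value = b + stats::rnorm(1, 0, sd_noise))
  }
  as_cohort_table(do.call(rbind, rows))
}

# textbook split-plot sums of squares, coded independently of the package's
# aov-based fitting path
splitplot_oracle <- function(tab) {
  Y <- tapply(tab$value, list(tab$subject_id, tab$condition), mean)
  grp <- tapply(as.character(tab$group), tab$subject_id, `[`, 1L)[rownames(Y)]
  k <- ncol(Y); n <- nrow(Y); gl <- sort(unique(grp)); g <- length(gl)
  m <- mean(Y)
  m_s <- rowMeans(Y)
  m_c <- colMeans(Y)
  m_g <- vapply(gl, function(x) mean(Y[grp == x, ]), numeric(1))
  m_gc <- t(vapply(gl, function(x) colMeans(Y[grp == x, , drop = FALSE]),
                   numeric(k)))
  n_g <- as.numeric(table(grp)[gl])
  ss_group <- k * sum(n_g * (m_g - m)^2)
  ss_serr <- k * sum((m_s - m_g[match(grp, gl)])^2)
  ss_cond <- n * sum((m_c - m)^2)
  ss_int <- sum(n_g * (m_gc - outer(m_g, rep(1, k)) -
                         outer(rep(1, g), m_c) + m)^2)
  resid <- Y - m_gc[match(grp, gl), ] - (m_s - m_g[match(grp, gl)])
  ss_werr <- sum(resid^2)
  list(
    F_group = (ss_group / (g - 1)) / (ss_serr / (n - g)),
    F_cond = (ss_cond / (k - 1)) / (ss_werr / ((n - g) * (k - 1))),
    F_int = (ss_int / ((g - 1) * (k - 1))) / (ss_werr / ((n - g) * (k - 1))))
}

balanced_integer_cohort <- function(seed = 33) {
  set.seed(seed)
  rows <- list()
  for (g in c("young", "pd", "stroke")) for (i in 1:4) {
    sid <- paste0(g, i)
    for (cc in c("ST", "SDT", "CDT"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = g, condition = cc,
        gait_speed_mps = 1, n_turns_used = 4, measure = "m",
        value = sample(0:20, 1))
  }
  as_cohort_table(do.call(rbind, rows))
}

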