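test_that("cop simulation is deterministic under seeding and linear in scale", {
  set.seed(3); a <- simulate_cop(0.05, duration_s = 2, fs = 128)
  set.seed(3); b <- simulate_cop(0.05, duration_s = 2, fs = 128)
  expect_identical(a, b)
  # the OU recursion is linear in the scale: same noise, doubled scale,
  # doubled trajectory
  set.seed(3); d <- simulate_cop(0.10, duration_s = 2, fs = 128)
  expect_equal(d$x, 2 * a$x, tolerance = 1e-12)
  expect_equal(average_velocity(d), 2 * average_velocity(a),
               tolerance = 1e-12)
})

test_that("mean av increases with sway scale over independent replicates", {
  set.seed(21)
  av_small <- replicate(200, average_velocity(simulate_cop(0.02, 1, 128)))
  av_big <- replicate(200, average_velocity(simulate_cop(0.04, 1, 128)))
  expect_gt(mean(av_big), mean(av_small))
})

test_that("sway scale near zero gives near-zero pl and av", {
  set.seed(5)
  tr <- simulate_cop(1e-9, duration_s = 2, fs = 128)
  expect_lt(path_length(tr), 1e-6)
  expect_lt(average_velocity(tr), 1e-6)
  expect_error(simulate_cop(0, 2, 128), "positive")
  expect_error(simulate_cop(-1, 2, 128), "positive")
  expect_error(simulate_cop(0.1, -2, 128), "positive")
})

test_that("calibration hits the per-condition targets and is symmetric", {
  cfg <- sim_config(seed = 13)
  sc <- calibrate_scales(cfg, n_traces = 300)
  # fresh batch, independent seed
  set.seed(1234)
  for (cond in c("EOSS", "ECFS")) {
    av <- replicate(300, average_velocity(
      simulate_cop(sc[[cond]], cfg$duration_s, cfg$fs)))
    target <- cfg$condition_av_targets[[cond]]
    expect_lt(abs(mean(av) - target) / target, 0.05)
  }
  cfg_eq <- sim_config(condition_av_targets = c(EOSS = 1, ECSS = 1,
                                                EOFS = 1, ECFS = 1),
                       seed = 13)
  sc_eq <- calibrate_scales(cfg_eq, n_traces = 100)
  expect_true(all(abs(sc_eq - sc_eq[[1]]) < 1e-12))
})

test_that("imu coupling: zero motion and zero noise give an all-zero recording", {
  cfg <- sim_config(site_noise_sd = c(ankle = 0, lumbar = 0, sternum = 0,
                                      wrist = 0, arm = 0),
                    seed = 1)
  flat <- cop_trace(rep(0, 256), rep(0, 256), fs = 128)
  set.seed(2)
  rec <- cop_to_imu(flat, "lumbar", "center", cfg)
  expect_true(all(rec$acc == 0))
  expect_equal(nrow(rec$acc), 256)
})

test_that("imu coupling: lumbar signal variance exceeds arm variance", {
  cfg <- sim_config(seed = 1)
  set.seed(31)
  wins <- 0
  for (i in 1:50) {
    cop <- simulate_cop(0.1, duration_s = 2, fs = 128)
    lum <- cop_to_imu(cop, "lumbar", "center", cfg)
    arm <- cop_to_imu(cop, "arm", "left", cfg)
    if (var(lum$acc[, "X"]) > max(apply(arm$acc, 2, var))) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("arm sensors carry ML motion on Y and AP motion on X", {
  cfg <- sim_config(site_noise_sd = c(ankle = 0, lumbar = 0, sternum = 0,
                                      wrist = 0, arm = 0),
                    site_gain_cv = c(ankle = 0, lumbar = 0, sternum = 0,
                                     wrist = 0, arm = 0),
                    seed = 1)
  ml_only <- cop_trace(sin(2 * pi * 4 * (0:255) / 128), rep(0, 256), fs = 128)
  arm <- cop_to_imu(ml_only, "arm", "right", cfg)
  lumbar <- cop_to_imu(ml_only, "lumbar", "center", cfg)
  expect_gt(sd(arm$acc[, "Y"]), 0)      # ML drive lands on Y for the arm
  expect_equal(sd(arm$acc[, "X"]), 0)   # no AP motion
  expect_gt(sd(lumbar$acc[, "X"]), 0)   # ... but on X elsewhere
  expect_equal(sd(lumbar$acc[, "Y"]), 0)
  expect_error(cop_to_imu(ml_only, "forehead", "center", cfg),
               "unknown placement")
})

test_that("cohort has the study shape and is seed-reproducible", {
  co <- shared_cohort()
  expect_s3_class(co, "sway_cohort")
  expect_length(co$subjects, 8)
  n_rec <- sum(vapply(co$subjects, function(s)
    sum(vapply(s$conditions, function(cn) length(cn$recordings), integer(1))),
    integer(1)))
  expect_identical(n_rec, 8L * 4L * 8L)
  # recordings share sample count with their cop trace
  s1 <- co$subjects[[1]]$conditions$EOSS
  expect_true(all(vapply(s1$recordings, function(r)
    nrow(r$acc) == length(s1$cop$x), logical(1))))
  co2 <- simulate_cohort(sim_config(n_subjects = 8, seed = 11))
  expect_identical(cohort_scores(co2), cohort_scores(co))
  expect_identical(co2$subjects[[3]]$conditions$ECFS$recordings$wrist_left$acc,
                   co$subjects[[3]]$conditions$ECFS$recordings$wrist_left$acc)
  expect_error(simulate_cohort(sim_config(n_subjects = 1)), ">= 2")
})

test_that("zero ability spread collapses between-subject av variance", {
  co <- simulate_cohort(sim_config(n_subjects = 6, condition_av_cv = 0,
                                   duration_jitter_sd = 0, seed = 5))
  s <- cohort_scores(co)
  for (cond in CTSIB_CONDITIONS) {
    av <- s$av_in_per_s[s$condition == cond]
    expect_lt(sd(av) / mean(av), 0.05)
  }
})

test_that("shared subject ability induces cross-condition av correlation", {
  co <- simulate_cohort(sim_config(seed = 17))  # default 34 subjects
  s <- cohort_scores(co)
  eoss <- s$av_in_per_s[s$condition == "EOSS"]
  ecss <- s$av_in_per_s[s$condition == "ECSS"]
  expect_gt(cor(eoss, ecss), 0.4)
  # difficulty ordering of the condition means
  m <- tapply(s$av_in_per_s, s$condition, mean)
  expect_true(m[["ECFS"]] > m[["EOFS"]] && m[["EOFS"]] > m[["ECSS"]] &&
                m[["ECSS"]] > m[["EOSS"]])
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(condition_av_targets = c(EOSS = 1, ECSS = 1,
                                                   EOFS = 1)),
               "named exactly")
  expect_error(sim_config(condition_av_targets = c(EOSS = -1, ECSS = 1,
                                                   EOFS = 1, ECFS = 1)),
               "positive")
  expect_error(sim_config(fs = 128, duration_s = 11.0001), "integer sample")
  expect_error(sim_config(left_handed_fraction = 1.5), "0, 1")
  expect_error(sim_config(site_gains = c(ankle = 0, lumbar = 1, sternum = 1,
                                         wrist = 1, arm = 1)),
               "positive")
})
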