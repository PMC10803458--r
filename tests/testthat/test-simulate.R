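test_that("configuration invariants are enforced with field names", {
  expect_error(gait_sim_config(duration = 0), "duration")
  expect_error(gait_sim_config(frame_rate = -1), "frame_rate")
  expect_error(gait_sim_config(step_period = 0), "step_period")
  expect_error(gait_sim_config(knee_rom = 180), "knee_rom")
  expect_error(gait_sim_config(noise_sd = -0.1), "noise_sd")
})

test_that("noise-free walks hit the programmed step length exactly", {
  # 0.6 s steps at 30 Hz land on the frame grid, so sampled peaks are exact
  sim <- generate_walk(gait_sim_config(duration = 10, step_length = 600,
                                       step_period = 0.6, noise_sd = 0))
  d <- inter_ankle_distance_series(sim$trajectory)
  pk <- detect_step_peaks(d, 30)
  expect_identical(nrow(pk), length(sim$ground_truth$true_step_times))
  expect_true(all(abs(pk$step_length - 600) < 1e-6))
  expect_true(all(is.finite(sim$trajectory$coords)))
  expect_identical(n_frames(sim$trajectory), 300L)
})

test_that("each knee oscillates once per stride across the programmed range", {
  cfg <- gait_sim_config(duration = 8, knee_rom = 74, noise_sd = 0)
  sim <- generate_walk(cfg)
  for (side in c("left", "right")) {
    theta <- knee_angle_series(sim$trajectory, side)$values
    expect_lte(max(theta), 180 + 1e-9)
    expect_gte(min(theta), 180 - 74 - 1e-9)
    expect_lt(abs(range_of_motion(knee_angle_series(sim$trajectory, side)) -
                    74), 0.5)
    # one peak-flexion dwell per stride (stride 1.2 s over 8 s)
    at_min <- theta <= 180 - 74 + 1e-6
    n_dwell <- sum(diff(c(FALSE, at_min)) == 1)
    expect_lte(abs(n_dwell - 8 / 1.2), 1.5)
  }
})

test_that("the same seed reproduces a walk bit for bit", {
  cfg <- gait_sim_config(duration = 3, noise_sd = 1.5, seed = 33)
  s1 <- generate_walk(cfg)
  s2 <- generate_walk(cfg)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  expect_identical(s1$ground_truth$true_step_times,
                   s2$ground_truth$true_step_times)
})

test_that("scale equivariance: scaling lengths scales recovered steps", {
  base <- gait_sim_config(duration = 6, step_length = 400, noise_sd = 0)
  scaled <- gait_sim_config(duration = 6, step_length = 400 * 1.5,
                            trunk_height = 500 * 1.5,
                            shank_length = 420 * 1.5,
                            thigh_length = 450 * 1.5, noise_sd = 0)
  p1 <- detect_step_peaks(
    inter_ankle_distance_series(generate_walk(base)$trajectory), 30)
  p2 <- detect_step_peaks(
    inter_ankle_distance_series(generate_walk(scaled)$trajectory), 30)
  expect_identical(p1$frame, p2$frame)
  expect_equal(p2$step_length, 1.5 * p1$step_length, tolerance = 1e-9)
})

test_that("ground-truth lists are mutually consistent", {
  gt <- generate_walk(gait_sim_config(duration = 10))$ground_truth
  m <- length(gt$true_step_times)
  expect_length(gt$true_step_lengths, m)
  expect_length(gt$true_step_sides, m)
  expect_true(all(diff(gt$true_step_times) > 0))
  expect_true(all(diff(gt$true_toe_off_times_left) > 0))
  expect_true(all(gt$true_heel_strike_times_right >= 0))
  expect_identical(dim(gt$true_com_path), c(300L, 3L))
})

test_that("sit-to-stand holds are static and the rise is monotone", {
  cfg <- gait_sim_config(duration = 6, noise_sd = 0)
  sim <- generate_sts(cfg)
  gt <- sim$ground_truth
  t <- frame_times(sim$trajectory)
  sac_z <- joint_xyz(sim$trajectory, "sacrum")[, 3]
  expect_lt(diff(range(sac_z[t < gt$rise_onset])), 1e-9)
  stand <- t >= gt$rise_offset & t < gt$descend_onset
  expect_lt(diff(range(sac_z[stand])), 1e-9)

  theta <- knee_angle_series(sim$trajectory, "left")$values
  rise <- t >= gt$rise_onset & t <= gt$rise_offset
  expect_true(all(diff(theta[rise]) >= -1e-9))
  expect_lt(abs(min(theta) - 90), 1)
  expect_lt(abs(max(theta) - 180), 1e-6)
  expect_error(generate_sts(gait_sim_config(duration = 3)), "duration")
})

test_that("sit-to-stand noise has the configured spread", {
  cfg0 <- gait_sim_config(duration = 5, noise_sd = 0)
  cfg5 <- gait_sim_config(duration = 5, noise_sd = 5, seed = 8)
  clean <- generate_sts(cfg0)$trajectory
  noisy <- generate_sts(cfg5)$trajectory
  dev <- as.numeric(noisy$coords - clean$coords)
  expect_lt(abs(sd(dev) - 5), 0.2 * 5)
})

test_that("add_noise is a pure, seeded perturbation", {
  traj <- generate_walk(gait_sim_config(duration = 2))$trajectory
  expect_identical(add_noise(traj, 0)$coords, traj$coords)
  n1 <- add_noise(traj, 3, seed = 5)
  n2 <- add_noise(traj, 3, seed = 5)
  expect_identical(n1$coords, n2$coords)
  expect_false(identical(n1$coords, traj$coords))
  # large-sample mean of the perturbation is near zero
  big <- generate_walk(gait_sim_config(duration = 10))$trajectory
  delta <- add_noise(big, 3, seed = 1)$coords - big$coords
  expect_lt(abs(mean(delta)), 0.5)
  expect_error(add_noise(traj, -1), "sd")
})

test_that("the full pipeline round-trips a noise-free walk", {
  cfg <- gait_sim_config(duration = 10, step_length = 480,
                         step_period = 0.66, knee_rom = 64, noise_sd = 0)
  sim <- generate_walk(cfg)
  ex <- extract_gait_parameters(sim$trajectory, default_profile())
  gt <- sim$ground_truth
  expect_identical(ex$n_steps, length(gt$true_step_times))
  expect_lt(abs(mean(ex$steps$step_length) - 480) / 480, 0.02)
  expect_lt(abs(mean(ex$steps$step_period, na.rm = TRUE) - 0.66), 1 / 30)
  expect_lt(abs(ex$parameters$left_knee_rom_deg - 64), 1)
  expect_identical(ex$steps$side, gt$true_step_sides)
})
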