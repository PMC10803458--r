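test_that("inter-ankle distance equals the Euclidean norm", {
  traj <- trajectory_from_joints(
    list(ankle_left = matrix(0, 2, 3),
         ankle_right = matrix(c(300, 0, 0), 2, 3, byrow = TRUE),
         head = matrix(c(0, 0, 1700), 2, 3, byrow = TRUE)), n = 2)
  expect_equal(inter_ankle_distance_series(traj), c(300, 300))
  rnd <- random_trajectory(20, seed = 13)
  d <- inter_ankle_distance_series(rnd)
  al <- joint_xyz(rnd, "ankle_left"); ar <- joint_xyz(rnd, "ankle_right")
  oracle <- vapply(1:20, function(i) sqrt(sum((al[i, ] - ar[i, ])^2)),
                   numeric(1))
  expect_identical(d, oracle)
})

test_that("step-peak detection applies the threshold rule", {
  expect_identical(nrow(detect_step_peaks(rep(5, 10), 30)), 0L)
  pk <- detect_step_peaks(c(100, 500, 100, 200, 100), 30,
                          threshold_fraction = 0.5)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$step_length, 500)
  expect_identical(pk$frame, 1L)  # 0-based
  expect_error(detect_step_peaks(c(1, 2), 30), "3 samples")
  expect_error(detect_step_peaks(c(1, 2, 1), 30, threshold_fraction = 1.2),
               "threshold_fraction")
})

test_that("anatomical planes satisfy the perpendicularity construction", {
  traj <- trajectory_from_joints(
    list(sacrum = matrix(c(0, 0, 1000), 2, 3, byrow = TRUE),
         spine = matrix(c(0, 10, 1300), 2, 3, byrow = TRUE),
         neck = matrix(c(0, 0, 1500), 2, 3, byrow = TRUE)), n = 2)
  pl <- compute_planes(traj, 0)
  expect_equal(abs(pl$sagittal$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(pl$coronal$normal), c(0, 1, 0), tolerance = 1e-12)

  collinear <- trajectory_from_joints(
    list(sacrum = matrix(c(0, 0, 1000), 2, 3, byrow = TRUE),
         spine = matrix(c(0, 0, 1300), 2, 3, byrow = TRUE),
         neck = matrix(c(0, 0, 1500), 2, 3, byrow = TRUE)), n = 2)
  expect_error(compute_planes(collinear, 1), "frame 1")

  # generic frames: coronal normal perpendicular to sagittal normal and to
  # the spine axis, both to 1e-9
  walk <- generate_walk(gait_sim_config(duration = 2))$trajectory
  for (i in c(0, 10, 30)) {
    pl <- compute_planes(walk, i)
    sv <- walk$coords[i + 1, 1, ]
    cv <- walk$coords[i + 1, match("neck", gait_joints()), ]
    axis <- (cv - sv) / sqrt(sum((cv - sv)^2))
    expect_lt(abs(sum(pl$coronal$normal * pl$sagittal$normal)), 1e-9)
    expect_lt(abs(sum(pl$coronal$normal * axis)), 1e-9)
    expect_equal(sqrt(sum(pl$coronal$normal^2)), 1, tolerance = 1e-12)
  }
})

test_that("step side goes to the anterior ankle and mirrors correctly", {
  mk <- function(flip = 1) {
    joints <- list(
      sacrum = rbind(c(0, 0, 1000), c(50, 0, 1000), c(100, 0, 1000)),
      spine = rbind(c(10, 0, 1300), c(60, 0, 1300), c(110, 0, 1300)),
      neck = rbind(c(0, 0, 1500), c(50, 0, 1500), c(100, 0, 1500)),
      ankle_left = rbind(c(0, 100, 0), c(150, 100, 0), c(160, 100, 0)),
      ankle_right = rbind(c(0, -100, 0), c(0, -100, 0), c(150, -100, 0))
    )
    if (flip < 0) {
      tmp <- joints$ankle_left; joints$ankle_left <- joints$ankle_right
      joints$ankle_right <- tmp
    }
    trajectory_from_joints(joints, n = 3)
  }
  peaks <- data.frame(frame = 1L, time = 1 / 30, step_length = 150)
  expect_identical(assign_step_side(mk(1), peaks), "left")
  expect_identical(assign_step_side(mk(-1), peaks), "right")
})

test_that("near-tied ankle distances raise the ambiguity warning", {
  joints <- list(
    sacrum = rbind(c(0, 0, 1000), c(50, 0, 1000), c(100, 0, 1000)),
    spine = rbind(c(10, 0, 1300), c(60, 0, 1300), c(110, 0, 1300)),
    neck = rbind(c(0, 0, 1500), c(50, 0, 1500), c(100, 0, 1500)),
    ankle_left = rbind(c(0, 100, 0), c(80.4, 100, 0), c(160, 100, 0)),
    ankle_right = rbind(c(0, -100, 0), c(80, -100, 0), c(150, -100, 0))
  )
  traj <- trajectory_from_joints(joints, n = 3)
  peaks <- data.frame(frame = 1L, time = 1 / 30, step_length = 1)
  expect_warning(side <- assign_step_side(traj, peaks), "ambiguous")
  expect_identical(side, "left")
})

test_that("step periods and speeds follow the difference formulas", {
  steps <- data.frame(time = c(1.0, 1.6), step_length = c(600, 600))
  out <- step_periods_and_speeds(steps)
  expect_true(is.na(out$step_period[1]) && is.na(out$walking_speed[1]))
  expect_equal(out$step_period[2], 0.6)
  expect_equal(out$walking_speed[2], 1000)
  expect_error(step_periods_and_speeds(
    data.frame(time = c(1, 1), step_length = c(1, 1))), "increasing")
})

test_that("gait phases follow the percentile and threshold rules", {
  # three strides of a sawtooth velocity: per stride (1 s at 30 Hz),
  # minimum -300 deg/s at t = 0.2, maximum +400 at t = 0.5, then a linear
  # fall crossing 10 deg/s just before t = 0.62, constant small after
  one <- approx(x = c(0, 0.1, 0.2, 0.35, 0.5, 0.6, 0.63, 1.0),
                y = c(0, -50, -300, 50, 400, 30, 5, 0),
                xout = seq(1 / 30, 1, by = 1 / 30))$y
  w <- rep(one, 3)
  omega <- structure(list(values = w, side = "left", frame_rate = 30),
                     class = "angular_velocity_series")
  ph <- detect_gait_phases(omega)
  expect_equal(length(ph$toe_off_times), 3)
  expect_true(all(abs(ph$toe_off_times - c(0.2, 1.2, 2.2)) < 1.01 / 30))
  # first sample at or below 10 deg/s after each maximum is near t = 0.62
  expect_true(all(abs(ph$heel_strike_times - c(0.62, 1.62, 2.62)) < 1.3 / 30))
  # records pair each toe-off with the next heel-strike
  expect_equal(ph$phases$t_swing, ph$phases$t_touch - ph$phases$t_split)
  expect_true(is.na(ph$phases$t_support[1]))
  expect_equal(ph$phases$t_support[-1],
               ph$phases$t_split[-1] - ph$phases$t_touch[-3],
               tolerance = 1e-9)
  expect_error(detect_gait_phases(
    structure(list(values = rep(1, 30), side = "left", frame_rate = 30),
              class = "angular_velocity_series")), "no gait")
})

test_that("phases of one foot alternate, increase and tile the stride", {
  sim <- generate_walk(gait_sim_config(duration = 10))
  om <- angular_velocity_series(knee_angle_series(sim$trajectory, "left"))
  ph <- detect_gait_phases(om)
  expect_true(all(diff(ph$toe_off_times) > 0))
  expect_true(all(diff(ph$heel_strike_times) > 0))
  # exactly one heel-strike between consecutive toe-offs
  to <- ph$toe_off_times; hs <- ph$heel_strike_times
  for (i in seq_len(length(to) - 1)) {
    expect_identical(sum(hs > to[i] & hs < to[i + 1]), 1L)
  }
  inner <- ph$phases[!is.na(ph$phases$t_support), ]
  stride <- 2 * 0.6
  expect_true(all(abs(inner$t_swing + inner$t_support - stride) <= 1 / 30))
})

test_that("event outputs are invariant to rigid translation", {
  sim <- generate_walk(gait_sim_config(duration = 6, seed = 2))
  traj <- sim$trajectory
  moved <- keypoint_trajectory(sweep(traj$coords, 3,
                                     c(500, -200, 90), "+"),
                               traj$frame_rate)
  d1 <- inter_ankle_distance_series(traj)
  d2 <- inter_ankle_distance_series(moved)
  expect_equal(d1, d2, tolerance = 1e-9)
  p1 <- detect_step_peaks(d1, 30); p2 <- detect_step_peaks(d2, 30)
  expect_equal(p1, p2, tolerance = 1e-9)
  expect_identical(assign_step_side(traj, p1), assign_step_side(moved, p2))
})
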