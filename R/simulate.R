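# Parametric 17-joint gait / sit-to-stand simulator with recorded ground
# truth. The limbs follow stylized kinematic waveforms (not a physics or
# biomechanical model): sufficient to exercise every extractor with known
# answers. Lab frame: +X walking direction, +Y left, +Z up, mm; frame i is
# at time i / frame_rate (0-based).

#' Simulation configuration
#'
#' @param duration Simulated time in s (> 0).
#' @param frame_rate Frames per second (default 30).
#' @param step_length Peak inter-ankle distance per step, mm.
#' @param step_period Time between consecutive steps, s.
#' @param knee_rom Peak knee flexion range per stride, degrees in
#'   `[0, 180)`: the knee angle oscillates between `180 - knee_rom` and 180
#'   once per stride.
#' @param stance_swing_ratio Ratio of support to swing time encoded in the
#'   knee waveform (default 1.5, i.e. a 60/40 gait cycle).
#' @param lateral_sway_amplitude Amplitude of the whole-body COM excursion
#'   relative to the body's sagittal plane, mm; the COM-to-sagittal-plane
#'   deviation spans `2 * amplitude` over a stride. An anteroposterior
#'   COM excursion at step frequency with twice this amplitude accompanies
#'   it (AP sway normally exceeds ML sway).
#' @param trunk_height Sacrum-to-head-top distance, mm.
#' @param shank_length,thigh_length Leg segment lengths, mm.
#' @param noise_sd Isotropic Gaussian keypoint noise SD, mm (>= 0).
#' @param seed Integer seed for the noise stream.
#' @return A validated list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(duration = 10, frame_rate = 30,
                            step_length = 600, step_period = 0.6,
                            knee_rom = 60, stance_swing_ratio = 1.5,
                            lateral_sway_amplitude = 10,
                            trunk_height = 500, shank_length = 420,
                            thigh_length = 450, noise_sd = 0, seed = 1L) {
  cfg <- list(duration = duration, frame_rate = frame_rate,
              step_length = step_length, step_period = step_period,
              knee_rom = knee_rom, stance_swing_ratio = stance_swing_ratio,
              lateral_sway_amplitude = lateral_sway_amplitude,
              trunk_height = trunk_height, shank_length = shank_length,
              thigh_length = thigh_length, noise_sd = noise_sd,
              seed = as.integer(seed))
  check <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid configuration: '", field, "' ", why,
                          call. = FALSE)
  }
  check(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  check(is.numeric(frame_rate) && frame_rate > 0, "frame_rate", "must be > 0")
  check(is.numeric(step_period) && step_period > 0, "step_period", "must be > 0")
  check(is.numeric(step_length) && step_length >= 0, "step_length", "must be >= 0")
  check(is.numeric(knee_rom) && knee_rom >= 0 && knee_rom < 180,
        "knee_rom", "must be in [0, 180)")
  check(is.numeric(stance_swing_ratio) && stance_swing_ratio > 0,
        "stance_swing_ratio", "must be > 0")
  check(is.numeric(lateral_sway_amplitude) && lateral_sway_amplitude >= 0,
        "lateral_sway_amplitude", "must be >= 0")
  check(is.numeric(trunk_height) && trunk_height > 0, "trunk_height", "must be > 0")
  check(is.numeric(shank_length) && shank_length > 0, "shank_length", "must be > 0")
  check(is.numeric(thigh_length) && thigh_length > 0, "thigh_length", "must be > 0")
  check(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(cfg, class = "gait_sim_config")
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<gait_sim_config> %gs @ %g Hz, step %g mm / %g s, ",
                     "knee ROM %g deg, noise %g mm (seed %d)\n"),
              x$duration, x$frame_rate, x$step_length, x$step_period,
              x$knee_rom, x$noise_sd, x$seed))
  invisible(x)
}

# ---- knee waveform -------------------------------------------------------
# theta(u) = 180 - (R/2) (1 - cos(2 pi w(u))) over the normalized stride
# phase u in [0,1). The warp w is piecewise linear with a dwell at peak
# flexion (w = 0.5) and at full extension (w = 1), so the sampled series
# attains both extremes exactly. A steep "toe-off burst" segment centred
# on w = 0.25 makes the angular-velocity minimum sharp and interior (the
# discrete argmin lands on the ground-truth toe-off instant), and the
# extension ramp is steep for the same reason. w_hs is placed where the
# continuous angular velocity crosses the canonical 10 deg/s heel-strike
# threshold.
knee_warp_nodes <- function(knee_rom, stride, stance_swing_ratio,
                            hs_threshold = 10) {
  sf <- 1 / (1 + stance_swing_ratio)        # swing fraction of the stride
  a1 <- 0.6 * (1 - sf)                       # stance before toe-off
  a2 <- 0.4 * (1 - sf)                       # stance after heel-strike
  u_to <- a1
  u_hs <- a1 + sf
  u_f <- u_to + 0.35 * sf                    # peak-flexion dwell start
  df <- 0.25 * sf                            # dwell length
  u_ext <- u_hs + 0.5 * a2                   # full-extension dwell start
  s_burst <- 2.5                             # w-slope of the toe-off burst
  h <- min(0.08, 0.45 * a1, 0.6 * (u_f - u_to))
  delta <- s_burst * h
  amp_coef <- (knee_rom / 2) * (2 * pi / stride)  # deg/s per (w' sin)
  l_ext <- 0.40 * sf
  w_hs <- 0.97
  if (amp_coef > 0) {
    for (it in 1:30) {
      s_ext <- (w_hs - 0.5) / l_ext
      arg <- min(0.999, hs_threshold / (amp_coef * s_ext))
      w_new <- 1 - asin(arg) / (2 * pi)
      if (abs(w_new - w_hs) < 1e-12) { w_hs <- w_new; break }
      w_hs <- w_new
    }
  }
  list(u = c(0, u_to - h, u_to + h, u_f, u_f + df, u_hs, u_ext, 1),
       w = c(0, 0.25 - delta, 0.25 + delta, 0.5, 0.5, w_hs, 1, 1),
       u_to = u_to, u_hs = u_hs)
}

knee_theta <- function(t, phase, stride, knee_rom, nodes) {
  u <- ((t - phase) / stride) %% 1
  w <- stats::approx(nodes$u, nodes$w, xout = u, rule = 2)$y
  180 - (knee_rom / 2) * (1 - cos(2 * pi * w))
}

# cosine ease for swing-foot advance: e(0)=0, e(1)=1, zero end velocity
swing_ease <- function(s) (1 - cos(pi * s)) / 2

# mass-weighted share of the swayed joints in the whole-body COM, used to
# convert a desired COM sway amplitude into a joint offset
sway_gain <- function(table = default_segment_table()) {
  fixed <- c("sacrum", "spine", "neck")
  sw <- function(j) as.numeric(!(j %in% fixed))
  share <- table$mass_fraction *
    ((1 - table$com_position_fraction) * vapply(table$proximal, sw, 1) +
       table$com_position_fraction * vapply(table$distal, sw, 1))
  c_share <- sum(share) / sum(table$mass_fraction)
  1 / c_share
}

#' Simulate a straight walk
#'
#' Generates a 17-joint walking trajectory with fully known ground truth:
#' the feet advance alternately so the peak inter-ankle distance of every
#' step equals `step_length` (noise-free), each knee oscillates once per
#' stride between `180 - knee_rom` and 180 degrees with toe-off and
#' heel-strike instants defined by the angular-velocity waveform, and the
#' whole-body COM sways laterally relative to the body's sagittal plane
#' with the configured amplitude. Turning is not simulated.
#'
#' @param config A [gait_sim_config()].
#' @return List with `trajectory` (a [keypoint_trajectory()], noisy if
#'   `noise_sd > 0`) and `ground_truth`: `true_step_lengths` (mm),
#'   `true_step_sides`, `true_step_times` (s), `true_knee_rom_left`,
#'   `true_knee_rom_right` (deg), `true_toe_off_times_left/right`,
#'   `true_heel_strike_times_left/right` (s), `true_com_path` (n x 3, mm,
#'   from the noise-free trajectory), and a `config` echo.
#' @export
generate_walk <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  f <- config$frame_rate
  n <- round(config$duration * f)
  if (n < 2) stop("invalid configuration: 'duration' too short for 2 frames",
                  call. = FALSE)
  t <- (seq_len(n) - 1) / f
  t_end <- t[n]
  p <- config$step_period
  stride <- 2 * p
  S <- config$step_length
  Ls <- config$shank_length
  Lt <- config$thigh_length
  Tr <- config$trunk_height

  # step schedule: peaks at T_k = (k+1) p while an interior peak fits
  t0 <- p
  m <- max(0, floor((t_end - 2 / f - t0) / p) + 1)
  T_steps <- t0 + (seq_len(m) - 1) * p

  # feet: right foot swings over (T_(k-1), T_k) for even k (0-based),
  # left for odd k; a foot advances 2 S per swing; the final partial swing
  # freezes at 65% progress, parking the inter-ankle distance well below
  # the step-peak threshold so no spurious boundary peak arises
  foot_x <- function(parity, base0) {
    x <- rep(base0, n)
    z <- numeric(n)
    base <- base0
    for (k in seq(parity, m, by = 2)) {
      t_start <- t0 + (k - 1) * p
      if (t_start >= t_end) break
      s <- pmin(0.65 * (k == m) + 1 * (k < m), pmax(0, (t - t_start) / p))
      in_or_after <- t > t_start
      x[in_or_after] <- base + 2 * S * swing_ease(s[in_or_after])
      z[in_or_after] <- 40 * sinpi(s[in_or_after])
      base <- base + 2 * S
    }
    list(x = x, z = z)
  }
  right <- foot_x(0, -S)
  left <- foot_x(1, 0)

  # knee waveforms, phased so each leg's swing is centred on its foot's
  # swing window
  nodes <- knee_warp_nodes(config$knee_rom, stride, config$stance_swing_ratio)
  u_mid <- (nodes$u_to + nodes$u_hs) / 2
  phase_left <- (t0 + p - p / 2) - u_mid * stride   # left lands at T_1
  phase_right <- phase_left - p
  theta_l <- knee_theta(t, phase_left, stride, config$knee_rom, nodes)
  theta_r <- knee_theta(t, phase_right, stride, config$knee_rom, nodes)

  coords <- array(0, dim = c(n, 17, 3))
  set_joint <- function(coords, joint, x, y, z) {
    ji <- joint_index(joint)
    coords[, ji, 1] <- x; coords[, ji, 2] <- y; coords[, ji, 3] <- z
    coords
  }
  build_leg <- function(coords, side, foot, theta) {
    legs <- leg_joints(side)
    flex <- (180 - theta) * pi / 180
    kx <- foot$x; kz <- foot$z + Ls
    coords <- set_joint(coords, legs$ankle, foot$x, 0, foot$z)
    coords <- set_joint(coords, legs$knee, kx, 0, kz)
    set_joint(coords, legs$hip, kx + Lt * sin(flex), 0, kz + Lt * cos(flex))
  }
  coords <- build_leg(coords, "right", right, theta_r)
  coords <- build_leg(coords, "left", left, theta_l)

  x_sac <- (left$x + right$x) / 2
  z_sac <- Ls + Lt + 80
  coords <- set_joint(coords, "sacrum", x_sac, 0, z_sac)
  coords <- set_joint(coords, "spine", x_sac + 30, 0, z_sac + 0.45 * Tr)
  coords <- set_joint(coords, "neck", x_sac, 0, z_sac + 0.80 * Tr)
  coords <- set_joint(coords, "head", x_sac, 0, z_sac + 0.90 * Tr)
  coords <- set_joint(coords, "head_top", x_sac, 0, z_sac + Tr)
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    coords <- set_joint(coords, paste0("shoulder_", side),
                        x_sac, sgn * 180, z_sac + 0.75 * Tr)
    coords <- set_joint(coords, paste0("elbow_", side),
                        x_sac, sgn * 190, z_sac + 0.75 * Tr - 280)
    coords <- set_joint(coords, paste0("wrist_", side),
                        x_sac, sgn * 185, z_sac + 0.75 * Tr - 280 - 250)
  }

  # COM sway: every joint except the three spine-plane anchors gets the
  # same offset, scaled so the whole-body COM excursion relative to the
  # sagittal plane spans [0, 2 * amplitude] laterally (stride frequency);
  # an anteroposterior component at step frequency with twice the lateral
  # amplitude accompanies it, as AP sway normally exceeds ML sway
  if (config$lateral_sway_amplitude > 0) {
    g <- sway_gain()
    s_t <- config$lateral_sway_amplitude * (1 + sin(2 * pi * t / stride))
    ap_t <- 2 * config$lateral_sway_amplitude * (1 + cos(2 * pi * t / p))
    swayed <- setdiff(gait_joints(), c("sacrum", "spine", "neck"))
    for (j in swayed) {
      coords[, joint_index(j), 2] <- coords[, joint_index(j), 2] + g * s_t
      coords[, joint_index(j), 1] <- coords[, joint_index(j), 1] + g * ap_t
    }
  }

  clean <- keypoint_trajectory(coords, f, "synthetic walk")
  com <- whole_body_com_series(clean)$com

  event_times <- function(phase, u_event) {
    j0 <- ceiling((0 - phase) / stride - u_event)
    j1 <- floor((t_end - phase) / stride - u_event)
    if (j1 < j0) return(numeric(0))
    phase + (seq(j0, j1) + u_event) * stride
  }

  gt <- list(
    true_step_lengths = rep(S, m),
    true_step_sides = rep(c("right", "left"), length.out = m),
    true_step_times = T_steps,
    true_knee_rom_left = config$knee_rom,
    true_knee_rom_right = config$knee_rom,
    true_toe_off_times_left = event_times(phase_left, nodes$u_to),
    true_toe_off_times_right = event_times(phase_right, nodes$u_to),
    true_heel_strike_times_left = event_times(phase_left, nodes$u_hs),
    true_heel_strike_times_right = event_times(phase_right, nodes$u_hs),
    true_com_path = com,
    config = unclass(config)
  )
  traj <- if (config$noise_sd > 0) {
    add_noise(clean, config$noise_sd, config$seed)
  } else clean
  list(trajectory = traj, ground_truth = gt)
}

#' Simulate a sit-to-stand movement
#'
#' Seated hold (1 s), a smooth monotone rise to standing, a standing hold
#' (1 s), a smooth descent, and a final seated hold. The knee angle rises
#' monotonically from about 90 degrees (seated) to 180 degrees (standing)
#' and back; the sacrum height is exactly constant during the holds.
#' Requires `duration >= 4` s.
#'
#' @param config A [gait_sim_config()]; `step_length`, `step_period` and
#'   sway are ignored.
#' @return List with `trajectory` and `ground_truth` (`rise_onset`,
#'   `rise_offset`, `descend_onset`, `descend_offset` in s, plus
#'   `true_com_path` and the `config` echo).
#' @export
generate_sts <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (config$duration < 4) {
    stop("invalid configuration: 'duration' must be >= 4 s for sit-to-stand",
         call. = FALSE)
  }
  f <- config$frame_rate
  n <- round(config$duration * f)
  t <- (seq_len(n) - 1) / f
  Ls <- config$shank_length; Lt <- config$thigh_length
  Tr <- config$trunk_height
  move <- (config$duration - 3) / 2
  rise_on <- 1; rise_off <- 1 + move
  desc_on <- rise_off + 1; desc_off <- desc_on + move

  smoothstep <- function(s) s^2 * (3 - 2 * s)
  prog <- numeric(n)
  idx <- t >= rise_on & t < rise_off
  prog[idx] <- smoothstep((t[idx] - rise_on) / move)
  prog[t >= rise_off & t < desc_on] <- 1
  idx <- t >= desc_on & t < desc_off
  prog[idx] <- 1 - smoothstep((t[idx] - desc_on) / move)
  theta <- 90 + 90 * prog                 # seated 90 deg -> standing 180 deg

  coords <- array(0, dim = c(n, 17, 3))
  set_joint <- function(coords, joint, x, y, z) {
    ji <- joint_index(joint)
    coords[, ji, 1] <- x; coords[, ji, 2] <- y; coords[, ji, 3] <- z
    coords
  }
  flex <- (180 - theta) * pi / 180
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    legs <- leg_joints(side)
    coords <- set_joint(coords, legs$ankle, 0, sgn * 100, 0)
    coords <- set_joint(coords, legs$knee, 0, sgn * 100, Ls)
    coords <- set_joint(coords, legs$hip, Lt * sin(flex), sgn * 100,
                        Ls + Lt * cos(flex))
  }
  hip_x <- Lt * sin(flex); hip_z <- Ls + Lt * cos(flex)
  coords <- set_joint(coords, "sacrum", hip_x, 0, hip_z + 60)
  coords <- set_joint(coords, "spine", hip_x + 30, 0, hip_z + 60 + 0.45 * Tr)
  coords <- set_joint(coords, "neck", hip_x, 0, hip_z + 60 + 0.80 * Tr)
  coords <- set_joint(coords, "head", hip_x, 0, hip_z + 60 + 0.90 * Tr)
  coords <- set_joint(coords, "head_top", hip_x, 0, hip_z + 60 + Tr)
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    coords <- set_joint(coords, paste0("shoulder_", side),
                        hip_x, sgn * 180, hip_z + 60 + 0.75 * Tr)
    coords <- set_joint(coords, paste0("elbow_", side),
                        hip_x, sgn * 190, hip_z + 60 + 0.75 * Tr - 280)
    coords <- set_joint(coords, paste0("wrist_", side),
                        hip_x, sgn * 185, hip_z + 60 + 0.75 * Tr - 530)
  }

  clean <- keypoint_trajectory(coords, f, "synthetic sit-to-stand")
  gt <- list(rise_onset = rise_on, rise_offset = rise_off,
             descend_onset = desc_on, descend_offset = desc_off,
             true_com_path = whole_body_com_series(clean)$com,
             config = unclass(config))
  traj <- if (config$noise_sd > 0) {
    add_noise(clean, config$noise_sd, config$seed)
  } else clean
  list(trajectory = traj, ground_truth = gt)
}

#' Add isotropic Gaussian keypoint noise
#'
#' Returns a new trajectory with iid N(0, sd^2) noise added to every
#' coordinate of every joint in every frame; the input is unchanged and
#' `sd = 0` returns an exact copy. Seeded and reproducible; the caller's
#' RNG state is untouched.
#'
#' @param traj A [keypoint_trajectory()].
#' @param sd Noise standard deviation in mm (>= 0).
#' @param seed Integer seed.
#' @return A new [keypoint_trajectory()].
#' @export
add_noise <- function(traj, sd, seed = 1L) {
  validate_trajectory(traj)
  if (sd < 0) stop("invalid configuration: 'sd' must be >= 0", call. = FALSE)
  if (sd == 0) return(traj)
  noise <- with_preserved_rng(seed,
                              array(stats::rnorm(length(traj$coords), 0, sd),
                                    dim = dim(traj$coords)))
  keypoint_trajectory(traj$coords + noise, traj$frame_rate, traj$source_label)
}
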