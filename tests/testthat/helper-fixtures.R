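# Shared fixtures: small trajectories built in code, a default subject
# profile matched to the simulator's skeleton, and event-comparison
# helpers.

default_profile <- function() {
  subject_profile("sim", 420, 420, 70, "healthy")
}

# random but valid trajectory (finite, proper dims)
random_trajectory <- function(n = 10, seed = 1, frame_rate = 30) {
  set.seed(seed)
  keypoint_trajectory(array(rnorm(n * 17 * 3, sd = 300), dim = c(n, 17, 3)),
                      frame_rate)
}

# trajectory from a named list of per-joint n x 3 matrices (defaults 0)
trajectory_from_joints <- function(joints, n, frame_rate = 30) {
  coords <- array(0, dim = c(n, 17, 3))
  for (nm in names(joints)) {
    ji <- match(nm, gait_joints())
    coords[, ji, ] <- joints[[nm]]
  }
  keypoint_trajectory(coords, frame_rate)
}

# worst matched-event error (in frames) over detected events lying inside
# the ground-truth span (+- one frame); boundary events whose true
# counterpart falls outside the recording are excluded
interior_event_error_frames <- function(detected, truth, frame_rate) {
  if (length(truth) == 0 || length(detected) == 0) return(0)
  keep <- detected >= min(truth) - 1 / frame_rate &
    detected <= max(truth) + 1 / frame_rate
  detected <- detected[keep]
  if (length(detected) == 0) return(0)
  max(vapply(detected, function(x) min(abs(x - truth)), numeric(1))) *
    frame_rate
}

# adjusted Rand index between two labellings (independent oracle helper)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
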