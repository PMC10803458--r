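# Trajectory preprocessing: body-frame centering, shank-anchored metric
# scaling, resampling, and cross-correlation time alignment.

#' Centre a trajectory on the sacrum
#'
#' Subtracts the sacrum position from every joint, frame by frame, so the
#' sacrum sits at the origin in every frame and all coordinates become
#' body-relative. Per-frame inter-joint distances are unchanged.
#'
#' @param traj A [keypoint_trajectory()].
#' @return A new centred [keypoint_trajectory()].
#' @export
center_keypoints <- function(traj) {
  validate_trajectory(traj)
  sac <- traj$coords[, joint_index("sacrum"), , drop = FALSE]  # n x 1 x 3
  coords <- sweep_frames(traj$coords, sac)
  keypoint_trajectory(coords, traj$frame_rate, traj$source_label)
}

# Subtract an n x 1 x 3 offset from an n x 17 x 3 array.
sweep_frames <- function(coords, offset) {
  out <- coords
  for (a in 1:3) out[, , a] <- coords[, , a] - offset[, 1, a]
  out
}

#' Scale a trajectory to measured shank lengths
#'
#' Monocular 3D poses are scale-ambiguous. Each frame is multiplied by the
#' ratio of the subject's measured shank length sum (left + right) to the
#' frame's computed knee-to-ankle length sum, so that afterwards every
#' frame's computed shank lengths add up to the measured lengths.
#'
#' @param traj A [keypoint_trajectory()].
#' @param profile A [subject_profile()] with measured shank lengths.
#' @param ratio `"frame"` (default) recomputes the ratio for every frame
#'   from that frame's knees and ankles; `"median"` applies the single
#'   median ratio of the whole trajectory as a smoother variant.
#' @return A new scaled [keypoint_trajectory()].
#' @export
scale_keypoints <- function(traj, profile, ratio = c("frame", "median")) {
  validate_trajectory(traj)
  ratio <- match.arg(ratio)
  measured <- profile$shank_length_left + profile$shank_length_right
  shank_sum <- computed_shank_sums(traj)
  bad <- which(shank_sum <= .Machine$double.eps)
  if (length(bad) > 0) {
    stop("degenerate geometry: zero shank length at frame ", bad[1] - 1,
         call. = FALSE)
  }
  r <- measured / shank_sum
  if (ratio == "median") r <- rep(stats::median(r), length(r))
  coords <- traj$coords * r  # recycles over the frame dimension
  keypoint_trajectory(coords, traj$frame_rate, traj$source_label)
}

# Per-frame sum of left and right knee-to-ankle distances (mm).
computed_shank_sums <- function(traj) {
  d <- function(a, b) {
    sqrt(rowSums((joint_xyz(traj, a) - joint_xyz(traj, b))^2))
  }
  d("knee_left", "ankle_left") + d("knee_right", "ankle_right")
}

#' Resample a trajectory to a new frame rate
#'
#' Linear interpolation of every coordinate onto the uniform grid
#' t = k / `f_target` spanning the original duration.
#'
#' @param traj A [keypoint_trajectory()].
#' @param f_target Target frame rate in Hz (> 0).
#' @return A resampled [keypoint_trajectory()] with `frame_rate = f_target`.
#' @export
resample_trajectory <- function(traj, f_target) {
  validate_trajectory(traj)
  if (!is.finite(f_target) || f_target <= 0) {
    stop("f_target must be a positive frame rate", call. = FALSE)
  }
  t_src <- frame_times(traj)
  t_max <- t_src[length(t_src)]
  t_out <- seq(0, by = 1 / f_target, length.out = floor(t_max * f_target + 1e-9) + 1)
  n_out <- length(t_out)
  coords <- array(NA_real_, dim = c(n_out, 17, 3))
  for (j in 1:17) {
    for (a in 1:3) {
      coords[, j, a] <- stats::approx(t_src, traj$coords[, j, a], xout = t_out,
                                      rule = 2)$y
    }
  }
  keypoint_trajectory(coords, f_target, traj$source_label)
}

#' Align two equally sampled signals by cross-correlation
#'
#' Computes the discrete cross-correlation of the mean-removed signals,
#' C(tau) = sum_t x(t) * y(t - tau), over all integer lags with at least
#' 50% overlap, and returns the lag maximising it. Ties are broken toward
#' the smallest |tau| (then the negative lag). With this sign convention a
#' delayed copy y(t) = x(t - k) yields `shift = -k`; shifting y by
#' `-shift` samples restores alignment.
#'
#' @param x,y Numeric vectors (>= 2 samples each) at the same sampling rate.
#' @return A list of class `alignment_result` with `shift` (integer lag)
#'   and `peak_correlation` (the maximising C value).
#' @export
align_signals <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("both signals need at least 2 samples", call. = FALSE)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  if (all(xc == 0) || all(yc == 0)) {
    stop("undefined alignment: constant or all-zero signal", call. = FALSE)
  }
  min_overlap <- ceiling(0.5 * min(length(x), length(y)))
  lags <- seq(-(length(y) - min_overlap), length(x) - min_overlap)
  cc <- vapply(lags, function(tau) {
    # overlap of x(t) with y(t - tau): t in [max(0, tau), ...]
    tx <- seq(max(1, 1 + tau), min(length(x), length(y) + tau))
    sum(xc[tx] * yc[tx - tau])
  }, numeric(1))
  best <- max(cc)
  cand <- lags[cc >= best - .Machine$double.eps * max(1, abs(best))]
  shift <- cand[order(abs(cand), cand)][1]
  structure(list(shift = as.integer(shift),
                 peak_correlation = best),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> shift = %d samples, peak C = %.6g\n",
              x$shift, x$peak_correlation))
  invisible(x)
}

#' Trim two trajectories to their aligned overlap
#'
#' Applies the integer-frame shift recovered by [align_signals()] (lag of
#' `y`-derived features relative to `x`-derived features) and returns both
#' trajectories cut to the overlapping frames.
#'
#' @param traj_x,traj_y Trajectories at the same frame rate.
#' @param shift Integer lag as returned by [align_signals()].
#' @return List with elements `x` and `y`, the trimmed trajectories.
#' @export
apply_alignment <- function(traj_x, traj_y, shift) {
  nx <- n_frames(traj_x); ny <- n_frames(traj_y)
  # y(t) matches x(t + shift): drop -shift leading frames of y (shift < 0)
  # or shift leading frames of x (shift > 0).
  if (shift < 0) {
    iy <- (1 - shift):ny; ix <- seq_len(nx)
  } else {
    ix <- (1 + shift):nx; iy <- seq_len(ny)
  }
  n <- min(length(ix), length(iy))
  sub <- function(traj, idx) {
    keypoint_trajectory(traj$coords[idx, , , drop = FALSE], traj$frame_rate,
                        traj$source_label)
  }
  list(x = sub(traj_x, ix[seq_len(n)]), y = sub(traj_y, iy[seq_len(n)]))
}
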