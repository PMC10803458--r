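# Knee kinematics: included 3-point knee angle, its first-difference
# angular velocity, and range statistics.

#' Knee angle series of one leg
#'
#' The included angle at the knee between the knee-to-hip and knee-to-ankle
#' vectors, per frame:
#' theta_i = acos( (K_iH_i . K_iA_i) / (|K_iH_i| |K_iA_i|) ), in degrees.
#' A straight leg gives 180 degrees. The angle is invariant to rigid
#' translation, rotation and uniform scaling of the trajectory.
#'
#' @param traj A [keypoint_trajectory()].
#' @param side `"left"` or `"right"`.
#' @param smooth_window Optional odd moving-average window (frames) applied
#'   to the angle series before it is returned. Default `0` = no smoothing;
#'   left off in all standard analyses, offered because noisy keypoints
#'   make the differentiated velocity noisy.
#' @return An object of class `angle_series`: list with `values` (degrees),
#'   `side`, `frame_rate`.
#' @export
knee_angle_series <- function(traj, side = c("left", "right"),
                              smooth_window = 0L) {
  validate_trajectory(traj)
  side <- match.arg(side)
  legs <- leg_joints(side)
  h <- joint_xyz(traj, legs$hip)
  k <- joint_xyz(traj, legs$knee)
  a <- joint_xyz(traj, legs$ankle)
  theta <- angle_between_rows(h - k, a - k)
  if (anyNA(theta)) {
    stop("degenerate geometry: zero-length thigh or shank at frame ",
         which(is.na(theta))[1] - 1, call. = FALSE)
  }
  if (smooth_window >= 2) {
    w <- as.integer(smooth_window)
    theta <- stats::filter(theta, rep(1 / w, w), sides = 2)
    theta <- as.numeric(theta)
    # shrink to the frames where the full window fits
    keep <- !is.na(theta)
    theta <- theta[keep]
  }
  structure(list(values = theta, side = side, frame_rate = traj$frame_rate),
            class = "angle_series")
}

# Angle (degrees) between corresponding rows of two n x 3 matrices.
# Returns NA where either row has zero length.
angle_between_rows <- function(u, v) {
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ok <- nu > 0 & nv > 0
  ct <- rep(NA_real_, nrow(u))
  ct[ok] <- rowSums(u[ok, , drop = FALSE] * v[ok, , drop = FALSE]) /
    (nu[ok] * nv[ok])
  ct <- pmin(1, pmax(-1, ct))
  acos(ct) * 180 / pi
}

#' Knee angular velocity series
#'
#' First differences of the angle series scaled by the frame rate:
#' omega_i = f * (theta_i - theta_(i-1)), signed, in degrees/s. The series
#' is indexed to the later frame of each pair, so it is one sample shorter
#' than the angle series (no zero padding).
#'
#' @param angles An `angle_series` from [knee_angle_series()].
#' @return An object of class `angular_velocity_series`: list with `values`
#'   (degrees/s), `side`, `frame_rate`.
#' @export
angular_velocity_series <- function(angles) {
  stopifnot(inherits(angles, "angle_series"))
  if (length(angles$values) < 2) stop("need at least 2 frames", call. = FALSE)
  structure(
    list(values = angles$frame_rate * diff(angles$values),
         side = angles$side, frame_rate = angles$frame_rate),
    class = "angular_velocity_series"
  )
}

#' Range of motion (max minus min) of a series
#'
#' @param series An `angle_series`, `angular_velocity_series`, or plain
#'   numeric vector.
#' @return Scalar range (degrees, or degrees/s for a velocity series).
#' @export
range_of_motion <- function(series) {
  v <- if (is.list(series)) series$values else series
  if (length(v) == 0) stop("empty series", call. = FALSE)
  max(v) - min(v)
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s knee, %d frames @ %g Hz, range %.1f deg\n",
              x$side, length(x$values), x$frame_rate, range_of_motion(x)))
  invisible(x)
}

#' @export
print.angular_velocity_series <- function(x, ...) {
  cat(sprintf(
    "<angular_velocity_series> %s knee, %d samples @ %g Hz, range %.0f deg/s\n",
    x$side, length(x$values), x$frame_rate, range_of_motion(x)))
  invisible(x)
}
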