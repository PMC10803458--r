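# Step detection and labelling: inter-ankle distance peaks (step length and
# timing), anatomical planes and step side, step periods and walking speed,
# and swing/support phases from knee angular velocity extrema.

#' Inter-ankle distance series
#'
#' Per-frame 3D Euclidean distance between the left and right ankle joints
#' (mm). Its prominent local maxima mark the instants of largest foot
#' separation, i.e. the steps.
#'
#' @param traj A [keypoint_trajectory()].
#' @return Numeric vector, one value per frame.
#' @export
inter_ankle_distance_series <- function(traj) {
  validate_trajectory(traj)
  sqrt(rowSums((joint_xyz(traj, "ankle_left") - joint_xyz(traj, "ankle_right"))^2))
}

#' Detect step peaks in an inter-ankle distance series
#'
#' Local maxima of the distance series with value at least
#' `threshold_fraction` times the series maximum; retained peaks are kept
#' at least `min_separation_s` apart (and never closer than 2 frames;
#' larger peaks win). The default separation of 0.2 s encodes that no
#' gait has two step peaks within 200 ms; keypoint noise otherwise
#' splinters one peak into neighbouring jitter maxima. A maximum must
#' exceed the
#' neighbouring distinct values; a run of equal values flanked by lower
#' ones counts as a single peak at its central frame (a peak falling
#' exactly between two samples produces such a 2-sample plateau), so a
#' constant series has no peaks. Each retained peak gives one step: its
#' frame, time, and step length (the peak distance).
#'
#' @param distances Numeric series from [inter_ankle_distance_series()].
#' @param frame_rate Frame rate in Hz used to convert frames to times.
#' @param threshold_fraction Fraction of the series maximum below which
#'   local maxima are discarded, in (0, 1). Default 0.5.
#' @param min_separation_s Minimum time between retained peaks in seconds
#'   (default 0.2; values below 2 frames are raised to 2 frames).
#' @return A data.frame with columns `frame` (0-based), `time` (s) and
#'   `step_length` (mm); zero rows when no peaks qualify.
#' @export
detect_step_peaks <- function(distances, frame_rate, threshold_fraction = 0.5,
                              min_separation_s = 0.2) {
  d <- as.numeric(distances)
  if (length(d) < 3) stop("series needs at least 3 samples", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  runs <- rle(d)
  nr <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(seq_len(nr) > 1L & seq_len(nr) < nr &
                  runs$values > c(Inf, runs$values[-nr]) &
                  runs$values > c(runs$values[-1], Inf))
  i <- as.integer(floor((starts[cand] + ends[cand]) / 2))
  i <- i[d[i] >= threshold_fraction * max(d)]
  # enforce the minimum separation, keeping larger peaks first
  sep <- max(2L, ceiling(min_separation_s * frame_rate))
  i <- i[order(-d[i], i)]
  kept <- integer(0)
  for (p in i) if (!any(abs(kept - p) < sep)) kept <- c(kept, p)
  kept <- sort(kept)
  data.frame(frame = kept - 1L, time = (kept - 1L) / frame_rate,
             step_length = d[kept])
}

#' Anatomical planes at one frame
#'
#' The sagittal plane passes through the sacral, thoracic and cervical
#' spine points (normal = unit cross product of sacrum-to-thoracic and
#' sacrum-to-cervical vectors); the coronal plane passes through the sacrum
#' with normal = unit cross product of the sagittal normal and the unit
#' sacrum-to-cervical vector, hence perpendicular to both the sagittal
#' plane and the spine axis.
#'
#' @param traj A [keypoint_trajectory()].
#' @param frame 0-based frame index.
#' @return A list of class `anatomical_planes` with `sagittal` and
#'   `coronal` (each a list `point`, `normal`) and `frame`.
#' @export
compute_planes <- function(traj, frame) {
  validate_trajectory(traj)
  i <- as.integer(frame) + 1L
  if (i < 1L || i > n_frames(traj)) stop("frame out of range", call. = FALSE)
  sv <- unname(traj$coords[i, joint_index("sacrum"), ])
  tv <- unname(traj$coords[i, joint_index("spine"), ])
  cv <- unname(traj$coords[i, joint_index("neck"), ])
  n_sag <- cross3(tv - sv, cv - sv)
  len <- sqrt(sum(n_sag^2))
  if (len < 1e-9 * max(1, sqrt(sum((tv - sv)^2)) * sqrt(sum((cv - sv)^2)))) {
    stop("degenerate geometry: collinear spine points at frame ", frame,
         call. = FALSE)
  }
  n_sag <- n_sag / len
  axis <- (cv - sv) / sqrt(sum((cv - sv)^2))
  n_cor <- cross3(n_sag, axis)
  n_cor <- n_cor / sqrt(sum(n_cor^2))
  structure(
    list(sagittal = list(point = sv, normal = n_sag),
         coronal = list(point = sv, normal = n_cor),
         frame = as.integer(frame)),
    class = "anatomical_planes"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Unsigned distance from point p to a plane (point + unit normal).
point_plane_distance <- function(p, plane) {
  abs(sum((p - plane$point) * plane$normal))
}

#' Assign a body side to each detected step
#'
#' At each step peak the step is attributed to the foot whose ankle lies
#' anterior to the coronal plane. "Anterior" is the unit horizontal sacrum
#' displacement over the enclosing step interval (previous to next peak);
#' supply the trajectory in lab coordinates (before sacrum centering) so
#' this displacement exists. When the sacrum moves less than 10 mm the
#' horizontal component of the coronal-plane normal is used as-is — its
#' orientation is then arbitrary, so body-relative inputs may come out
#' globally side-flipped. If the two ankles' signed
#' distances differ by less than 1 mm a warning is raised and the ankle
#' with the larger absolute distance wins.
#'
#' @param traj A [keypoint_trajectory()].
#' @param peaks Step table from [detect_step_peaks()].
#' @return Character vector of `"left"` / `"right"`, one per step.
#' @export
assign_step_side <- function(traj, peaks) {
  validate_trajectory(traj)
  if (nrow(peaks) == 0) return(character(0))
  frames <- peaks$frame + 1L
  sac <- joint_xyz(traj, "sacrum")
  vapply(seq_along(frames), function(k) {
    i <- frames[k]
    i_prev <- if (k > 1) frames[k - 1] else 1L
    i_next <- if (k < length(frames)) frames[k + 1] else n_frames(traj)
    disp <- sac[i_next, ] - sac[i_prev, ]
    disp[3] <- 0
    planes <- compute_planes(traj, i - 1L)
    if (sqrt(sum(disp^2)) >= 10) {
      anterior <- disp / sqrt(sum(disp^2))
    } else {
      anterior <- planes$coronal$normal
      anterior[3] <- 0
      if (sum(anterior^2) == 0) {
        stop("cannot orient anterior direction at frame ", i - 1L, call. = FALSE)
      }
      anterior <- anterior / sqrt(sum(anterior^2))
    }
    n_cor <- planes$coronal$normal
    if (sum(n_cor * anterior) < 0) n_cor <- -n_cor
    sv <- planes$coronal$point
    s_l <- sum((traj$coords[i, joint_index("ankle_left"), ] - sv) * n_cor)
    s_r <- sum((traj$coords[i, joint_index("ankle_right"), ] - sv) * n_cor)
    if (abs(s_l - s_r) < 1) {
      warning("ambiguous step side at frame ", i - 1L,
              ": ankle distances within 1 mm", call. = FALSE)
      return(if (abs(s_l) >= abs(s_r)) "left" else "right")
    }
    if (s_l > s_r) "left" else "right"
  }, character(1))
}

#' Step periods and walking speeds
#'
#' Adds the step period p_i = T_i - T_(i-1) (s) and walking speed
#' v_i = (S_i + S_(i-1)) / (2 p_i) (mm/s) to a step table ordered by time.
#' The first step has no predecessor and gets `NA` for both.
#'
#' @param steps A data.frame with columns `time` (strictly increasing) and
#'   `step_length`, e.g. from [detect_step_peaks()].
#' @return The input with `step_period` and `walking_speed` columns added.
#' @export
step_periods_and_speeds <- function(steps) {
  if (nrow(steps) < 2) stop("need at least 2 steps", call. = FALSE)
  if (any(diff(steps$time) <= 0)) {
    stop("step times must be strictly increasing", call. = FALSE)
  }
  p <- c(NA_real_, diff(steps$time))
  v <- c(NA_real_,
         (steps$step_length[-1] + steps$step_length[-nrow(steps)]) / (2 * p[-1]))
  steps$step_period <- p
  steps$walking_speed <- v
  steps
}

#' Detect gait phases from a knee angular velocity series
#'
#' All strict local maxima and minima of the angular velocity are located;
#' maxima at or above the 80th percentile of the velocity values and minima
#' at or below the 20th percentile are retained (linear-interpolation
#' percentiles). Where consecutive retained extrema of the same kind occur
#' with none of the other kind between them, only the most extreme one is
#' kept, so toe-offs and heel-strike seeds alternate. Each retained minimum
#' marks a toe-off; from each retained maximum, scanning forward, the first
#' sample with velocity below `heel_strike_threshold` marks a heel-strike.
#' Swing time is a heel-strike minus the most recent preceding toe-off;
#' support time is a toe-off minus the most recent preceding heel-strike
#' (no value where no predecessor exists).
#'
#' @param omega An `angular_velocity_series` from
#'   [angular_velocity_series()].
#' @param heel_strike_threshold Velocity threshold in degrees/s
#'   (default 10).
#' @param absolute If `TRUE`, heel-strike uses |velocity| < threshold
#'   instead of the signed comparison.
#' @param q_low,q_high Percentile cutoffs for retained minima / maxima
#'   (defaults 0.2 and 0.8).
#' @return A list of class `gait_phases`: `toe_off_times`,
#'   `heel_strike_times` (s), `side`, and `phases`, a data.frame with one
#'   row per toe-off/next-heel-strike pair (`t_split`, `t_touch`,
#'   `t_swing`, `t_support`; `t_support` is `NA` for the first record).
#' @export
detect_gait_phases <- function(omega, heel_strike_threshold = 10,
                               absolute = FALSE, q_low = 0.2, q_high = 0.8) {
  stopifnot(inherits(omega, "angular_velocity_series"))
  w <- omega$values
  f <- omega$frame_rate
  n <- length(w)
  if (n < 3) stop("no gait detected: series too short", call. = FALSE)
  # velocity sample i (R index) spans angle frames i-1, i -> time i / f
  times <- seq_len(n) / f
  interior <- 2:(n - 1)
  is_max <- w[interior] > w[interior - 1] & w[interior] > w[interior + 1]
  is_min <- w[interior] < w[interior - 1] & w[interior] < w[interior + 1]
  maxima <- interior[is_max]
  minima <- interior[is_min]
  thr <- stats::quantile(w, c(q_low, q_high), names = FALSE, type = 7)
  maxima <- maxima[w[maxima] >= thr[2]]
  minima <- minima[w[minima] <= thr[1]]
  if (length(maxima) == 0 && length(minima) == 0) {
    stop("no gait detected: no retained velocity extrema", call. = FALSE)
  }
  ext <- alternate_extrema(maxima, minima, w)
  maxima <- ext$maxima; minima <- ext$minima
  toe_off <- times[minima]
  heel_strike <- unique(vapply(maxima, function(m) {
    j <- m + seq_len(n - m)
    hit <- if (absolute) which(abs(w[j]) < heel_strike_threshold) else
      which(w[j] < heel_strike_threshold)
    if (length(hit) == 0) NA_real_ else times[j[hit[1]]]
  }, numeric(1)))
  heel_strike <- sort(heel_strike[!is.na(heel_strike)])
  phases <- build_phase_records(toe_off, heel_strike)
  structure(list(toe_off_times = toe_off, heel_strike_times = heel_strike,
                 side = omega$side, phases = phases),
            class = "gait_phases")
}

# Keep only the most extreme of consecutive same-kind extrema so that
# maxima and minima alternate in time.
alternate_extrema <- function(maxima, minima, w) {
  ev <- rbind(
    data.frame(idx = maxima, kind = rep("max", length(maxima))),
    data.frame(idx = minima, kind = rep("min", length(minima)))
  )
  ev <- ev[order(ev$idx), , drop = FALSE]
  keep <- logical(nrow(ev))
  i <- 1
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$kind[j + 1] == ev$kind[i]) j <- j + 1
    run <- i:j
    best <- if (ev$kind[i] == "max") run[which.max(w[ev$idx[run]])] else
      run[which.min(w[ev$idx[run]])]
    keep[best] <- TRUE
    i <- j + 1
  }
  ev <- ev[keep, , drop = FALSE]
  list(maxima = ev$idx[ev$kind == "max"], minima = ev$idx[ev$kind == "min"])
}

build_phase_records <- function(toe_off, heel_strike) {
  if (length(toe_off) == 0) {
    return(data.frame(t_split = numeric(0), t_touch = numeric(0),
                      t_swing = numeric(0), t_support = numeric(0)))
  }
  rows <- lapply(toe_off, function(ts) {
    nxt <- heel_strike[heel_strike > ts]
    if (length(nxt) == 0) return(NULL)
    tt <- nxt[1]
    prev_touch <- heel_strike[heel_strike < ts]
    sup <- if (length(prev_touch) == 0) NA_real_ else ts - max(prev_touch)
    data.frame(t_split = ts, t_touch = tt, t_swing = tt - ts, t_support = sup)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(t_split = numeric(0), t_touch = numeric(0),
               t_swing = numeric(0), t_support = numeric(0))
}

#' @export
print.gait_phases <- function(x, ...) {
  cat(sprintf("<gait_phases> %s leg: %d toe-offs, %d heel-strikes\n",
              x$side, length(x$toe_off_times), length(x$heel_strike_times)))
  invisible(x)
}
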