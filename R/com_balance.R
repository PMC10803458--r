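# 11-segment whole-body centre of mass, relative COM velocity, and COM
# deviation ranges from the sagittal/coronal planes.

#' Default 11-segment anthropometric table
#'
#' The body is divided into 11 segments (head, upper trunk, lower trunk,
#' and bilateral upper arms, forearms, thighs, shanks); hands and feet are
#' excluded as the lightest parts. Each segment runs from a proximal to a
#' distal registry joint; its centre of mass sits at
#' `com_position_fraction` of the way from proximal to distal, and it
#' carries `mass_fraction` of the body mass. Mass fractions follow a
#' published adult segmental table (trunk split between an upper and a
#' lower segment); COM position fractions default to the midpoint. The
#' table is plain data and deliberately editable: supply your own (e.g.
#' population-specific standards) wherever a `segment_table` argument is
#' accepted. A CSV copy ships in `inst/extdata/segment_table.csv`.
#'
#' @return data.frame with columns `segment`, `proximal`, `distal`,
#'   `mass_fraction`, `com_position_fraction`.
#' @export
default_segment_table <- function() {
  data.frame(
    segment = c("head", "upper_trunk", "lower_trunk",
                "upper_arm_left", "upper_arm_right",
                "forearm_left", "forearm_right",
                "thigh_left", "thigh_right",
                "shank_left", "shank_right"),
    proximal = c("neck", "neck", "spine",
                 "shoulder_left", "shoulder_right",
                 "elbow_left", "elbow_right",
                 "hip_left", "hip_right",
                 "knee_left", "knee_right"),
    distal = c("head_top", "spine", "sacrum",
               "elbow_left", "elbow_right",
               "wrist_left", "wrist_right",
               "knee_left", "knee_right",
               "ankle_left", "ankle_right"),
    mass_fraction = c(0.081, 0.216, 0.281,
                      0.028, 0.028, 0.016, 0.016,
                      0.100, 0.100, 0.0465, 0.0465),
    com_position_fraction = rep(0.5, 11),
    stringsAsFactors = FALSE
  )
}

validate_segment_table <- function(table) {
  needed <- c("segment", "proximal", "distal", "mass_fraction",
              "com_position_fraction")
  if (!all(needed %in% names(table))) {
    stop("segment table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) != 11L) stop("segment table must have exactly 11 segments", call. = FALSE)
  if (any(table$mass_fraction <= 0 | table$mass_fraction >= 1) ||
      any(table$com_position_fraction < 0 | table$com_position_fraction > 1)) {
    stop("segment fractions out of range", call. = FALSE)
  }
  if (sum(table$mass_fraction) > 1 + 1e-12) {
    stop("segment mass fractions exceed 1", call. = FALSE)
  }
  joint_index(unique(c(table$proximal, table$distal)))
  table
}

#' Read a segment table from CSV or JSON
#' @param path File with the columns of [default_segment_table()].
#' @return Validated segment table data.frame.
#' @export
read_segment_table <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_segment_table(tab)
}

#' Per-segment centres of mass at one frame
#'
#' Each segment COM is the affine point
#' `proximal + com_position_fraction * (distal - proximal)`.
#'
#' @param traj A [keypoint_trajectory()].
#' @param table Segment table (default [default_segment_table()]).
#' @param frame 0-based frame index.
#' @return 11 x 3 matrix of segment COM coordinates (mm), rownames =
#'   segment names.
#' @export
segment_com <- function(traj, table = default_segment_table(), frame) {
  validate_trajectory(traj)
  table <- validate_segment_table(table)
  i <- as.integer(frame) + 1L
  if (i < 1L || i > n_frames(traj)) stop("frame out of range", call. = FALSE)
  p <- traj$coords[i, joint_index(table$proximal), , drop = FALSE]
  d <- traj$coords[i, joint_index(table$distal), , drop = FALSE]
  out <- matrix(NA_real_, nrow(table), 3,
                dimnames = list(table$segment, c("x", "y", "z")))
  for (a in 1:3) {
    out[, a] <- p[1, , a] + table$com_position_fraction * (d[1, , a] - p[1, , a])
  }
  out
}

#' Whole-body centre-of-mass series
#'
#' Combines the 11 segment COMs into a per-frame whole-body COM. The
#' default `"normalized"` variant is the standard segmental method
#' COM = sum(m_i COM_i) / sum(m_i) over the 11 included segments. The
#' `"printed"` variant is (1/N) sum(COM_i m_i / m_w) with N = 11 and m_w
#' the whole body mass — a literal transcription kept for fidelity testing;
#' it is not a centroid because hands and feet are excluded from the sum
#' while m_w and the 1/N prefactor refer to the whole body.
#'
#' @param traj A [keypoint_trajectory()].
#' @param table Segment table (default [default_segment_table()]).
#' @param profile A [subject_profile()]; only the `"printed"` variant uses
#'   the body mass (fractions make it cancel, but it is kept for clarity).
#' @param variant `"normalized"` (default) or `"printed"`.
#' @return An object of class `com_series`: list with `com` (n x 3 matrix,
#'   mm), `frame_rate`, `variant`.
#' @export
whole_body_com_series <- function(traj, table = default_segment_table(),
                                  profile = NULL,
                                  variant = c("normalized", "printed")) {
  validate_trajectory(traj)
  table <- validate_segment_table(table)
  variant <- match.arg(variant)
  total <- sum(table$mass_fraction)
  if (total <= 0) stop("zero total included mass", call. = FALSE)
  n <- n_frames(traj)
  pj <- joint_index(table$proximal)
  dj <- joint_index(table$distal)
  fr <- table$com_position_fraction
  w <- if (variant == "normalized") table$mass_fraction / total else
    table$mass_fraction / nrow(table)
  com <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (a in 1:3) {
    seg <- traj$coords[, pj, a] * (1 - rep(fr, each = n)) +
      traj$coords[, dj, a] * rep(fr, each = n)
    com[, a] <- as.numeric(seg %*% w)
  }
  structure(list(com = com, frame_rate = traj$frame_rate, variant = variant),
            class = "com_series")
}

#' Relative centre-of-mass velocity series
#'
#' RCOMV_a = f * ||COM_a - COM_(a-1)||: the frame-rate-scaled magnitude of
#' the per-frame COM displacement (mm/s), computed in a body-relative frame
#' defined by a reference point that is subtracted first. The reference is
#' the left ankle in system-validation work (it matches well-tracked foot
#' markers) and the sacrum/hip centre in measurement work.
#'
#' @param com A `com_series` from [whole_body_com_series()].
#' @param traj The [keypoint_trajectory()] the COM came from; needed unless
#'   `reference = "none"`.
#' @param reference `"sacrum"` (hip region, default), `"left_ankle"`, or
#'   `"none"` (use the COM coordinates as they are).
#' @return Numeric vector of length `n_frames - 1` (mm/s); element a
#'   corresponds to the displacement into frame a (0-based frame a >= 1).
#' @export
rcomv_series <- function(com, traj = NULL,
                         reference = c("sacrum", "left_ankle", "none")) {
  stopifnot(inherits(com, "com_series"))
  reference <- match.arg(reference)
  pos <- com$com
  if (reference != "none") {
    if (is.null(traj)) stop("traj is required for a joint reference", call. = FALSE)
    refj <- if (reference == "sacrum") "sacrum" else "ankle_left"
    pos <- pos - joint_xyz(traj, refj)
  }
  if (nrow(pos) < 2) stop("need at least 2 frames", call. = FALSE)
  com$frame_rate * sqrt(rowSums(diff(pos)^2))
}

#' COM deviation ranges from the sagittal and coronal planes
#'
#' For each frame, the unsigned point-to-plane distance from the whole-body
#' COM to that frame's sagittal and coronal planes; returns the range
#' (max - min) of each deviation series.
#'
#' @param com A `com_series` from [whole_body_com_series()].
#' @param traj The [keypoint_trajectory()] providing the per-frame spine
#'   points for [compute_planes()].
#' @return List with `sagittal_range`, `coronal_range` (mm) and the
#'   per-frame `sagittal_deviation`, `coronal_deviation` series.
#' @export
plane_deviation_ranges <- function(com, traj) {
  stopifnot(inherits(com, "com_series"))
  validate_trajectory(traj)
  n <- nrow(com$com)
  if (n != n_frames(traj)) stop("COM series and trajectory disagree in length", call. = FALSE)
  sag <- numeric(n); cor <- numeric(n)
  for (i in seq_len(n)) {
    planes <- compute_planes(traj, i - 1L)
    sag[i] <- point_plane_distance(com$com[i, ], planes$sagittal)
    cor[i] <- point_plane_distance(com$com[i, ], planes$coronal)
  }
  list(sagittal_range = max(sag) - min(sag),
       coronal_range = max(cor) - min(cor),
       sagittal_deviation = sag, coronal_deviation = cor)
}

#' @export
print.com_series <- function(x, ...) {
  cat(sprintf("<com_series> %d frames @ %g Hz (%s variant)\n",
              nrow(x$com), x$frame_rate, x$variant))
  invisible(x)
}
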