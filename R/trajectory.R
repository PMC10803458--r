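# Keypoint trajectory container and file I/O.
#
# A trajectory is an n_frames x 17 x 3 array of joint positions in mm plus
# a frame rate. The CSV dialect is one row per frame: a "frame" column
# followed by "<joint>_<axis>" columns with axes x, y, z; JSON mirrors it.

#' Construct a keypoint trajectory
#'
#' @param coords Numeric array `n_frames x 17 x 3` (mm), joints ordered as
#'   [gait_joints()], axes x, y, z.
#' @param frame_rate Sampling rate in Hz (> 0).
#' @param source_label Free-text provenance label.
#' @return An object of class `keypoint_trajectory` with elements `coords`,
#'   `frame_rate`, `joint_names`, `source_label`.
#' @export
keypoint_trajectory <- function(coords, frame_rate, source_label = "") {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 17L || dim(coords)[3] != 3L) {
    stop("coords must be an n_frames x 17 x 3 array", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, gait_joints(), c("x", "y", "z"))
  obj <- structure(
    list(coords = coords, frame_rate = as.numeric(frame_rate),
         joint_names = gait_joints(), source_label = source_label),
    class = "keypoint_trajectory"
  )
  validate_trajectory(obj)
}

validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (n_frames(traj) < 2L) stop("trajectory needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(traj$coords))) stop("trajectory contains non-finite coordinates", call. = FALSE)
  if (!is.finite(traj$frame_rate) || traj$frame_rate <= 0) {
    stop("frame_rate must be a positive number", call. = FALSE)
  }
  if (!identical(traj$joint_names, gait_joints())) {
    stop("joint order does not match the shared registry", call. = FALSE)
  }
  traj
}

#' Number of frames in a trajectory
#' @param traj A [keypoint_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame timestamps of a trajectory
#'
#' Frames are 0-based in time: frame i is at t = i / frame_rate seconds.
#' @param traj A [keypoint_trajectory()].
#' @return Numeric vector of times in seconds.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) / traj$frame_rate

#' Extract one joint's coordinate series
#' @param traj A [keypoint_trajectory()].
#' @param joint Joint name from [gait_joints()].
#' @return `n_frames x 3` numeric matrix (mm).
#' @export
joint_xyz <- function(traj, joint) {
  traj$coords[, joint_index(joint), , drop = TRUE]
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf(
    "<keypoint_trajectory> %d frames x 17 joints @ %g Hz (%.2f s)%s\n",
    n_frames(x), x$frame_rate, (n_frames(x) - 1) / x$frame_rate,
    if (nzchar(x$source_label)) paste0("  [", x$source_label, "]") else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.keypoint_trajectory <- function(x, ...) {
  n <- n_frames(x)
  out <- data.frame(frame = seq_len(n) - 1L)
  for (j in gait_joints()) {
    for (a in c("x", "y", "z")) {
      out[[paste(j, a, sep = "_")]] <- x$coords[, j, a]
    }
  }
  out
}

trajectory_column_names <- function() {
  as.vector(t(outer(gait_joints(), c("x", "y", "z"), paste, sep = "_")))
}

# Assemble a trajectory from a frame-by-column data.frame.
trajectory_from_table <- function(tab, frame_rate, source_label, path = "<table>") {
  wanted <- trajectory_column_names()
  missing <- setdiff(wanted, names(tab))
  if (length(missing) > 0) {
    stop("format error in '", path, "': missing joint column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(tab)
  if (n < 2L) stop("parse error in '", path, "': fewer than 2 frames", call. = FALSE)
  coords <- array(NA_real_, dim = c(n, 17, 3))
  for (ji in seq_along(gait_joints())) {
    for (ai in 1:3) {
      col <- paste(gait_joints()[ji], c("x", "y", "z")[ai], sep = "_")
      v <- tab[[col]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
        stop("parse error in '", path, "': non-numeric value in column '",
             col, "' at row ", if (is.na(bad)) "?" else bad, call. = FALSE)
      }
      coords[, ji, ai] <- v
    }
  }
  keypoint_trajectory(coords, frame_rate, source_label)
}

#' Read a keypoint trajectory from CSV or JSON
#'
#' CSV: one row per frame, a `frame` column then `<joint>_<axis>` columns
#' (axes `x`, `y`, `z`, mm), comma separator, `.` decimal, UTF-8.
#' JSON: an object with fields `frame_rate` and `frames` mirroring the same
#' columns (as written by [write_trajectory()]).
#'
#' @param path File path (`.csv` or `.json`).
#' @param frame_rate Sampling rate in Hz. Required for CSV; for JSON the
#'   file's own rate is used unless overridden here.
#' @return A [keypoint_trajectory()].
#' @export
read_trajectory <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fr <- if (!is.null(frame_rate)) frame_rate else obj$frame_rate
    tab <- as.data.frame(obj$frames)
    trajectory_from_table(tab, fr, obj$source_label %||% basename(path), path)
  } else {
    if (is.null(frame_rate)) stop("frame_rate is required when reading CSV", call. = FALSE)
    tab <- utils::read.csv(path, check.names = FALSE)
    trajectory_from_table(tab, frame_rate, basename(path), path)
  }
}

#' Write a keypoint trajectory to CSV or JSON
#'
#' @param traj A [keypoint_trajectory()].
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(frame_rate = traj$frame_rate, source_label = traj$source_label,
           frames = as.data.frame(traj)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a subject profile
#'
#' Measured anthropometrics of one subject: the shank (lower leg) lengths
#' anchor the metric scaling of scale-ambiguous monocular poses, the body
#' mass drives the segmental centre-of-mass weighting.
#'
#' @param subject_id Subject identifier.
#' @param shank_length_left,shank_length_right Measured knee-to-ankle
#'   lengths in mm (> 0).
#' @param body_mass Body mass in kg (> 0).
#' @param group Cohort label, `"healthy"` or `"patient"`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, shank_length_left, shank_length_right,
                            body_mass, group = c("healthy", "patient")) {
  group <- match.arg(group)
  if (shank_length_left <= 0 || shank_length_right <= 0) {
    stop("shank lengths must be positive", call. = FALSE)
  }
  if (body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         shank_length_left = as.numeric(shank_length_left),
         shank_length_right = as.numeric(shank_length_right),
         body_mass = as.numeric(body_mass), group = group),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (%s): shanks %g/%g mm, mass %g kg\n",
              x$subject_id, x$group, x$shank_length_left,
              x$shank_length_right, x$body_mass))
  invisible(x)
}

#' Read / write subject profiles as JSON
#'
#' JSON keys: `subject_id`, `L_left_mm`, `L_right_mm`, `mass_kg`, `group`.
#' @param path File path.
#' @return [read_subject_profile()] returns a [subject_profile()];
#'   [write_subject_profile()] returns `path` invisibly.
#' @export
read_subject_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_profile(obj$subject_id, obj$L_left_mm, obj$L_right_mm,
                  obj$mass_kg, obj$group)
}

#' @param profile A [subject_profile()].
#' @rdname read_subject_profile
#' @export
write_subject_profile <- function(profile, path) {
  jsonlite::write_json(
    list(subject_id = profile$subject_id,
         L_left_mm = profile$shank_length_left,
         L_right_mm = profile$shank_length_right,
         mass_kg = profile$body_mass, group = profile$group),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
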