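# Shared 17-joint skeleton registry. Every module indexes joints through
# this ordering; trajectory files must provide exactly these joints.

#' The 17-joint skeleton registry
#'
#' Joint names, in the fixed order used throughout the package, for the
#' common monocular-lifting skeleton layout: the spine column (sacrum,
#' thoracic spine, cervical neck, head, head top) and bilateral hip, knee,
#' ankle, shoulder, elbow and wrist joints.
#'
#' The axis convention for trajectories is +X = walking direction,
#' +Y = subject's left, +Z = up, all coordinates in millimetres.
#'
#' @return Character vector of 17 joint names.
#' @export
#' @examples
#' gait_joints()
gait_joints <- function() {
  c(
    "sacrum",
    "hip_right", "knee_right", "ankle_right",
    "hip_left", "knee_left", "ankle_left",
    "spine", "neck", "head", "head_top",
    "shoulder_left", "elbow_left", "wrist_left",
    "shoulder_right", "elbow_right", "wrist_right"
  )
}

# Index of one joint in the registry; errors on unknown names.
joint_index <- function(joint) {
  idx <- match(joint, gait_joints())
  if (anyNA(idx)) {
    stop("unknown joint(s): ", paste(joint[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

# Per-side joint triplet used by the knee-angle extractor.
leg_joints <- function(side) {
  side <- match.arg(side, c("left", "right"))
  list(
    hip = paste0("hip_", side),
    knee = paste0("knee_", side),
    ankle = paste0("ankle_", side)
  )
}
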