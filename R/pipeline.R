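# End-to-end workflows: parameter extraction from one trajectory segment,
# and the simulate / extract / validate / cluster commands that tie the
# stages together with manifests and deterministic seeds.

#' Extract all gait parameters from one trajectory segment
#'
#' Runs the full measurement chain on a single pre-edited straight-walk
#' segment: sacrum centering, shank-length scaling, knee angle and angular
#' velocity per side, step detection from inter-ankle distance peaks, step
#' side / period / speed, swing and support phases from angular-velocity
#' extrema, the 11-segment COM with RCOMV, and the COM deviation ranges
#' from the per-frame sagittal and coronal planes.
#'
#' @param traj A [keypoint_trajectory()].
#' @param profile A [subject_profile()].
#' @param threshold_fraction Step-peak threshold (see
#'   [detect_step_peaks()]).
#' @param heel_strike_threshold Heel-strike velocity threshold in deg/s.
#' @param com_variant `"normalized"` or `"printed"` (see
#'   [whole_body_com_series()]).
#' @param reference RCOMV reference point: `"sacrum"` (measurement mode,
#'   default) or `"left_ankle"` (validation mode).
#' @param scale_ratio `"frame"` or `"median"` (see [scale_keypoints()]).
#' @param segment_table Segment table for the COM model.
#' @return List of class `gait_extraction`: `parameters` (one-row
#'   data.frame of the summary parameters), `steps` (per-step table),
#'   `phases` (per-side [detect_gait_phases()] results), `n_steps`.
#' @export
extract_gait_parameters <- function(traj, profile,
                                    threshold_fraction = 0.5,
                                    heel_strike_threshold = 10,
                                    com_variant = "normalized",
                                    reference = c("sacrum", "left_ankle"),
                                    scale_ratio = "frame",
                                    segment_table = default_segment_table()) {
  reference <- match.arg(reference)
  prep <- scale_keypoints(center_keypoints(traj), profile, ratio = scale_ratio)

  ang <- list(left = knee_angle_series(prep, "left"),
              right = knee_angle_series(prep, "right"))
  om <- lapply(ang, angular_velocity_series)

  d <- inter_ankle_distance_series(prep)
  peaks <- detect_step_peaks(d, prep$frame_rate, threshold_fraction)
  if (nrow(peaks) < 2) {
    stop("no gait detected: fewer than 2 step peaks in segment", call. = FALSE)
  }
  # sides need the lab-frame sacrum motion, which centering removes
  peaks$side <- assign_step_side(traj, peaks)
  steps <- step_periods_and_speeds(peaks)

  phases <- lapply(om, detect_gait_phases,
                   heel_strike_threshold = heel_strike_threshold)

  com <- whole_body_com_series(prep, table = segment_table, profile = profile,
                               variant = com_variant)
  rcomv <- rcomv_series(com, prep, reference = reference)
  dev <- plane_deviation_ranges(com, prep)

  parameters <- data.frame(
    avg_step_period_s = mean(steps$step_period, na.rm = TRUE),
    avg_step_length_mm = mean(steps$step_length),
    avg_walking_speed_mm_s = mean(steps$walking_speed, na.rm = TRUE),
    right_knee_rom_deg = range_of_motion(ang$right),
    left_knee_rom_deg = range_of_motion(ang$left),
    right_knee_av_range_deg_s = range_of_motion(om$right),
    left_knee_av_range_deg_s = range_of_motion(om$left),
    avg_rcomv_mm_s = mean(rcomv),
    sagittal_dev_range_mm = dev$sagittal_range,
    coronal_dev_range_mm = dev$coronal_range
  )
  structure(list(parameters = parameters, steps = steps, phases = phases,
                 n_steps = nrow(steps)),
            class = "gait_extraction")
}

#' @export
print.gait_extraction <- function(x, ...) {
  cat(sprintf("<gait_extraction> %d steps\n", x$n_steps))
  print(round(as.data.frame(t(x$parameters)), 3))
  invisible(x)
}

write_manifest <- function(out_dir, command, config_list) {
  jsonlite::write_json(
    list(command = command,
         package_version = as.character(utils::packageVersion("gaitbalance")),
         config = config_list),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
}

#' Simulate a movement and write it to disk
#'
#' Writes the trajectory (CSV), the ground truth (JSON) and a manifest
#' echoing the configuration and seed; identical configurations produce
#' byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [gait_sim_config()].
#' @param task `"walk"` or `"sts"`.
#' @param prefix File-name prefix (default the task name).
#' @return Named list of written paths (`trajectory`, `ground_truth`,
#'   `manifest`), invisibly.
#' @export
run_simulate <- function(out_dir, config = gait_sim_config(),
                         task = c("walk", "sts"), prefix = NULL) {
  task <- match.arg(task)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  prefix <- prefix %||% task
  sim <- if (task == "walk") generate_walk(config) else generate_sts(config)
  paths <- list(
    trajectory = file.path(out_dir, paste0(prefix, "_trajectory.csv")),
    ground_truth = file.path(out_dir, paste0(prefix, "_ground_truth.json")),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trajectory(sim$trajectory, paths$trajectory)
  gt <- sim$ground_truth
  gt$true_com_path <- as.data.frame(gt$true_com_path)
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, paste("simulate", task), unclass(config))
  invisible(paths)
}

#' Extract a parameter table from trajectory segments
#'
#' One input file (or in-memory trajectory) is one pre-edited segment;
#' each yields one parameter row. Video editing/segment selection is not
#' automated.
#'
#' @param trajectories List of [keypoint_trajectory()] objects or file
#'   paths readable by [read_trajectory()].
#' @param profile A [subject_profile()] (shared) or list of profiles, one
#'   per segment.
#' @param frame_rate Frame rate for CSV inputs.
#' @param out_dir If non-`NULL`, the table is written there as
#'   `parameters.csv` together with a manifest.
#' @param ... Passed to [extract_gait_parameters()].
#' @return data.frame with one row per segment: `subject_id`, `segment_id`,
#'   `group`, `n_steps`, and the parameter columns.
#' @export
run_extract <- function(trajectories, profile, frame_rate = 30,
                        out_dir = NULL, ...) {
  if (inherits(trajectories, "keypoint_trajectory") ||
      is.character(trajectories)) {
    trajectories <- as.list(trajectories)
  }
  profiles <- if (inherits(profile, "subject_profile")) {
    rep(list(profile), length(trajectories))
  } else profile
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    label <- if (is.character(tr)) tr else paste0("segment_", i)
    if (is.character(tr)) tr <- read_trajectory(tr, frame_rate)
    ex <- tryCatch(
      extract_gait_parameters(tr, profiles[[i]], ...),
      error = function(e) stop("in segment '", label, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    cbind(data.frame(subject_id = profiles[[i]]$subject_id,
                     segment_id = label, group = profiles[[i]]$group,
                     n_steps = ex$n_steps),
          ex$parameters)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "extract", list(frame_rate = frame_rate))
  }
  out
}

#' Validate a test capture system against gold-standard trajectories
#'
#' For each paired segment: the gold trajectory is resampled to the test
#' frame rate, the pair is temporally aligned by cross-correlating the
#' left-knee angle series, both are trimmed to the aligned overlap, and
#' all gait parameters are extracted from each. Across segments, each
#' parameter is then scored with ICC(2,k) (targets = segments, raters =
#' the two systems) and Pearson r, with the conventional qualitative
#' bands.
#'
#' @param gold,test Equal-length lists of [keypoint_trajectory()] objects
#'   (or file paths), paired by position.
#' @param profile A [subject_profile()] or list of profiles per segment.
#' @param frame_rate Frame rate for CSV file inputs.
#' @param ... Passed to [extract_gait_parameters()]; the RCOMV reference
#'   defaults to the left ankle in this validation workflow.
#' @return List of class `reliability_report`: `report` (per-parameter
#'   data.frame with `icc`, `icc_band`, `r`, `r_band`, `p`),
#'   `delay_frames` (per pair, positive = test lags gold), `gold_table`,
#'   `test_table`.
#' @export
run_validate <- function(gold, test, profile, frame_rate = 30, ...) {
  if (inherits(gold, "keypoint_trajectory")) gold <- list(gold)
  if (inherits(test, "keypoint_trajectory")) test <- list(test)
  if (length(gold) != length(test)) {
    stop("pairing error: ", length(gold), " gold vs ", length(test),
         " test segments", call. = FALSE)
  }
  profiles <- if (inherits(profile, "subject_profile")) {
    rep(list(profile), length(gold))
  } else profile
  dots <- list(...)
  if (is.null(dots$reference)) dots$reference <- "left_ankle"

  delays <- integer(length(gold))
  gold_rows <- list(); test_rows <- list()
  for (i in seq_along(gold)) {
    g <- gold[[i]]; s <- test[[i]]
    if (is.character(g)) g <- read_trajectory(g, frame_rate)
    if (is.character(s)) s <- read_trajectory(s, frame_rate)
    g <- resample_trajectory(g, s$frame_rate)
    kg <- knee_angle_series(g, "left")$values
    ks <- knee_angle_series(s, "left")$values
    al <- align_signals(kg, ks)
    delays[i] <- -al$shift
    pair <- apply_alignment(g, s, al$shift)
    gold_rows[[i]] <- do.call(extract_gait_parameters,
                              c(list(pair$x, profiles[[i]]), dots))$parameters
    test_rows[[i]] <- do.call(extract_gait_parameters,
                              c(list(pair$y, profiles[[i]]), dots))$parameters
  }
  gold_table <- do.call(rbind, gold_rows)
  test_table <- do.call(rbind, test_rows)
  report <- do.call(rbind, lapply(names(gold_table), function(pn) {
    icc <- icc_2k(cbind(gold_table[[pn]], test_table[[pn]]))
    pv <- pearson_validity(gold_table[[pn]], test_table[[pn]])
    data.frame(parameter = pn, icc = icc$icc, icc_band = icc$band,
               r = pv$r, r_band = pv$band, p = pv$p)
  }))
  structure(list(report = report, delay_frames = delays,
                 gold_table = gold_table, test_table = test_table),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  out <- x$report
  out$icc <- round(out$icc, 3); out$r <- round(out$r, 3)
  out$p <- signif(out$p, 2)
  print(out, row.names = FALSE)
  cat("pair delays (frames):", paste(x$delay_frames, collapse = ", "), "\n")
  invisible(x)
}

#' Stratify a parameter table by k-means++ clustering
#'
#' Standardized k-means++ clustering (default k = 3) of the numeric
#' parameter columns, with clusters labelled by descending centroid
#' walking speed (level 1 = fastest); in a healthy/patient cohort the
#' fastest cluster captures the healthy-like gait and the remaining
#' clusters grade the patients' balance-recovery levels.
#'
#' @param table Parameter table (e.g. from [run_extract()] or
#'   [synthetic_reference_cohort()]).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the k-means++ seeding.
#' @param speed_col Column used to order the clusters.
#' @param ... Passed to [kmeanspp_cluster()].
#' @return List of class `stratification_report`: `clusters` (the
#'   [kmeanspp_cluster()] report), `levels` (per-row 1..k, 1 = fastest
#'   centroid), `centroid_speeds` (original units, descending).
#' @export
run_cluster <- function(table, k = 3, seed = 1L,
                        speed_col = "avg_walking_speed_mm_s", ...) {
  if (!speed_col %in% names(table)) {
    stop("schema error: missing column '", speed_col, "'", call. = FALSE)
  }
  rep_ <- kmeanspp_cluster(table, k = k, seed = seed, ...)
  ci <- match(speed_col, rep_$features)
  speeds <- rep_$centroids[, ci] * rep_$scaling$sd[ci] + rep_$scaling$center[ci]
  ord <- order(-speeds)
  levels_map <- match(seq_len(k), ord)
  structure(list(clusters = rep_, levels = levels_map[rep_$assignments],
                 centroid_speeds = speeds[ord]),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("<stratification_report> k = %d, level sizes: %s\n",
              x$clusters$k,
              paste(tabulate(x$levels, x$clusters$k), collapse = "/")))
  cat("centroid walking speeds (fast -> slow):",
      paste(round(x$centroid_speeds, 1), collapse = ", "), "\n")
  invisible(x)
}
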