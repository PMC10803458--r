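# Published reference summary statistics from the motivating clinical
# validation of smartphone markerless gait capture against an
# optical-marker gold standard (healthy adults and patients with
# musculoskeletal disorders). Shipped as plain data so that reliability
# discrepancies, Welch comparisons and synthetic cohorts can be recomputed
# without access to the raw recordings, which were not deposited.

#' Reference validation-experiment summaries (gold standard vs phone)
#'
#' Group means (SD) of each gait parameter computed from the same walks by
#' the optical-marker system ("vicon") and the smartphone system ("phone"),
#' with the published ICC(2,k) of each system and the between-system
#' Pearson r.
#'
#' @return data.frame with columns `parameter`, `unit`, `vicon_mean`,
#'   `vicon_sd`, `vicon_icc`, `phone_mean`, `phone_sd`, `phone_icc`, `r`.
#' @export
reference_validation_summary <- function() {
  data.frame(
    parameter = c("avg_step_period_s", "avg_walking_speed_mm_s",
                  "right_knee_rom_deg", "left_knee_rom_deg",
                  "right_knee_av_range_deg_s", "left_knee_av_range_deg_s",
                  "avg_rcomv_mm_s"),
    unit = c("s", "mm/s", "deg", "deg", "deg/s", "deg/s", "mm/s"),
    vicon_mean = c(0.71, 753, 55.8, 55.2, 518, 482, 906),
    vicon_sd = c(0.05, 68.7, 6.46, 9.38, 53.7, 103, 111),
    vicon_icc = c(0.946, 0.918, 0.982, 0.957, 0.942, 0.947, 0.853),
    phone_mean = c(0.73, 696, 56.0, 55.6, 525, 490, 899),
    phone_sd = c(0.06, 68.9, 3.87, 6.74, 42.9, 100, 127),
    phone_icc = c(0.965, 0.898, 0.937, 0.927, 0.975, 0.843, 0.839),
    r = c(0.898, 0.942, 0.953, 0.973, 0.808, 0.934, 0.978),
    stringsAsFactors = FALSE
  )
}

#' Reference measurement-experiment group summaries
#'
#' Group means (SD) of each smartphone-derived gait parameter for healthy
#' adults and for patients with musculoskeletal disorders in the
#' measurement experiment (gait-test segments; 4 segments per subject,
#' 13 healthy and 12 patient subjects, hence the default analysis sizes
#' 52 and 48 used by [reference_welch_tests()]).
#'
#' @return data.frame with columns `parameter`, `unit`, `healthy_mean`,
#'   `healthy_sd`, `patient_mean`, `patient_sd`.
#' @export
reference_measurement_summary <- function() {
  data.frame(
    parameter = c("avg_step_period_s", "avg_step_length_mm",
                  "avg_walking_speed_mm_s",
                  "right_knee_rom_deg", "left_knee_rom_deg",
                  "right_knee_av_range_deg_s", "left_knee_av_range_deg_s",
                  "avg_rcomv_mm_s",
                  "sagittal_dev_range_mm", "coronal_dev_range_mm"),
    unit = c("s", "mm", "mm/s", "deg", "deg", "deg/s", "deg/s", "mm/s",
             "mm", "mm"),
    healthy_mean = c(0.54, 605, 1131, 74.2, 73.5, 808, 808, 6.90, 1.52, 3.69),
    healthy_sd = c(0.04, 42.2, 81.4, 4.36, 5.47, 87.2, 89.8, 0.62, 0.24, 0.59),
    patient_mean = c(0.71, 416, 644, 58.5, 58.1, 554, 585, 5.77, 2.15, 4.51),
    patient_sd = c(0.12, 85.9, 169, 11.1, 12.6, 154, 173, 1.03, 0.58, 0.73),
    stringsAsFactors = FALSE
  )
}

#' Welch's t per parameter from the reference group summaries
#'
#' Applies [welch_t_summary()] to every row of
#' [reference_measurement_summary()] (healthy minus patients).
#'
#' @param n_healthy,n_patient Group sizes at the analysis-segment level
#'   (defaults 52 and 48).
#' @return data.frame with `parameter`, `t`, `df`, `p`.
#' @export
reference_welch_tests <- function(n_healthy = 52, n_patient = 48) {
  ref <- reference_measurement_summary()
  res <- lapply(seq_len(nrow(ref)), function(i) {
    w <- welch_t_summary(ref$healthy_mean[i], ref$healthy_sd[i], n_healthy,
                         ref$patient_mean[i], ref$patient_sd[i], n_patient)
    data.frame(parameter = ref$parameter[i], t = w$t, df = w$df, p = w$p)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Between-system discrepancies of the reference validation means
#'
#' Differences of the phone and gold-standard group means of
#' [reference_validation_summary()]: step-period error (s), mean
#' left/right knee-ROM error (deg), walking-speed error (mm/s and cm/s),
#' the larger of the two knee angular-velocity range errors (deg/s), and
#' the COM-velocity error (mm/s).
#'
#' @return Named list of scalar discrepancies.
#' @export
validation_discrepancies <- function() {
  ref <- reference_validation_summary()
  g <- function(p, col) ref[ref$parameter == p, col]
  err <- function(p) abs(g(p, "phone_mean") - g(p, "vicon_mean"))
  list(
    step_period_error_s = err("avg_step_period_s"),
    knee_rom_mean_error_deg = mean(c(err("right_knee_rom_deg"),
                                     err("left_knee_rom_deg"))),
    walking_speed_error_mm_s = err("avg_walking_speed_mm_s"),
    walking_speed_error_cm_s = err("avg_walking_speed_mm_s") / 10,
    angular_velocity_max_error_deg_s = max(err("right_knee_av_range_deg_s"),
                                           err("left_knee_av_range_deg_s")),
    rcomv_error_mm_s = err("avg_rcomv_mm_s")
  )
}

#' Synthetic cohort drawn from the reference group summaries
#'
#' Builds a synthetic parameter table mimicking the measurement
#' experiment: for each group, each parameter column is drawn
#' independently from a Gaussian with that group's reference mean and SD.
#' Column correlations of real gait data are NOT reproduced; the table is
#' a stand-in for the undeposited cohort, suitable for exercising the
#' statistics layer and for qualitative clustering checks.
#'
#' @param seed Integer seed (caller's RNG state untouched).
#' @param n_healthy,n_patient Rows per group (defaults 52 and 48).
#' @return data.frame with a `group` factor column and one numeric column
#'   per reference parameter.
#' @export
synthetic_reference_cohort <- function(seed = 1L, n_healthy = 52,
                                       n_patient = 48) {
  ref <- reference_measurement_summary()
  with_preserved_rng(seed, {
    cols <- lapply(seq_len(nrow(ref)), function(i) {
      c(stats::rnorm(n_healthy, ref$healthy_mean[i], ref$healthy_sd[i]),
        stats::rnorm(n_patient, ref$patient_mean[i], ref$patient_sd[i]))
    })
    names(cols) <- ref$parameter
    out <- as.data.frame(cols)
    out$group <- factor(rep(c("healthy", "patient"), c(n_healthy, n_patient)))
    out
  })
}
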