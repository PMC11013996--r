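#' @title Trial-level analysis pipeline
#' @description
#' Convenience wrapper running the standard chain on one recorded or
#' simulated trial: signal extraction, optional SSA detrending, period
#' estimation, repetition segmentation, exercise-specific ROM measures with
#' normative comparison, angular velocity and guideline checks.
#' @name pipeline
NULL

#' Segmentation driver signal of a trial
#'
#' The signal that drives period estimation and repetition segmentation:
#' the maximum-variance basic-keypoint signal among the image-plane (x, y)
#' axes -- depth is excluded because monocular z estimates are unreliable.
#' For side steps, where the legs alternate, the combined lateral ankle
#' deviation (sum of both ankles' absolute x-excursions) is used so that
#' every single step forms one cycle.
#'
#' @param seq a \code{pose_sequence} (or a precomputed basic-signal list).
#' @param exercise known exercise code, or NULL.
#' @return A \code{motion_signal}.
#' @export
segmentation_signal <- function(seq, exercise = NULL) {
  basic <- if (inherits(seq, "pose_sequence"))
    select_basic_signals(extract_signals(seq)) else seq
  fs <- basic[[1]]$fs
  if (identical(exercise, "SS")) {
    lx <- basic[["left_leg_x"]]$values
    rx <- basic[["right_leg_x"]]$values
    v <- abs(lx - stats::median(lx)) + abs(rx - stats::median(rx))
    return(motion_signal(v, fs, label = c("ss_lateral", "xy")))
  }
  xy <- basic[grepl("_(x|y)$", names(basic))]
  vars <- vapply(xy, function(s) stats::var(s$values), numeric(1))
  xy[[which.max(vars)]]
}

calib_frames <- function(seq, calib_s = 0.3) {
  max(2L, min(n_frames(seq), ceiling(calib_s * seq$fps)))
}

apparent_shoulder_width <- function(seq) {
  abs(seq$landmarks[, lm_row(BLAZEPOSE[["left_shoulder"]]), "x"] -
        seq$landmarks[, lm_row(BLAZEPOSE[["right_shoulder"]]), "x"])
}

apparent_trunk_length <- function(seq) {
  sy <- (seq$landmarks[, lm_row(BLAZEPOSE[["left_shoulder"]]), "y"] +
           seq$landmarks[, lm_row(BLAZEPOSE[["right_shoulder"]]), "y"]) / 2
  hy <- (seq$landmarks[, lm_row(BLAZEPOSE[["left_hip"]]), "y"] +
           seq$landmarks[, lm_row(BLAZEPOSE[["right_hip"]]), "y"]) / 2
  hy - sy
}

#' Trunk rotation / flexion angle series over a trial
#'
#' Foreshortening-based frontal-plane angle traces; calibration widths are
#' the median over the trial's first \code{calib_s} seconds (rest posture).
#'
#' @param seq a \code{pose_sequence}.
#' @param calib_s calibration window in seconds.
#' @return An \code{angle_series} (degrees, unsigned).
#' @export
trunk_rotation_series <- function(seq, calib_s = 0.3) {
  w <- apparent_shoulder_width(seq)
  calib <- stats::median(w[seq_len(calib_frames(seq, calib_s))])
  vals <- acos(pmin(1, pmax(0, w / calib))) * 180 / pi
  structure(list(values = vals, fs = seq$fps, joint = NULL),
            class = "angle_series")
}

#' @rdname trunk_rotation_series
#' @export
trunk_flexion_series <- function(seq, calib_s = 0.3) {
  l <- apparent_trunk_length(seq)
  calib <- stats::median(l[seq_len(calib_frames(seq, calib_s))])
  vals <- acos(pmin(1, pmax(0, l / calib))) * 180 / pi
  structure(list(values = vals, fs = seq$fps, joint = NULL),
            class = "angle_series")
}

# the angle traces and measurement conventions of each exercise
exercise_measures <- function(seq, exercise) {
  tri <- function(nm) do.call(joint_triplet, as.list(JOINT_TRIPLETS[[nm]]))
  switch(exercise,
    SS = list(
      hip_abduction_left = list(series = angle_series(seq, tri("left_hip_long")),
                                mode = "excursion", norm = "hip_abduction"),
      hip_abduction_right = list(series = angle_series(seq, tri("right_hip_long")),
                                 mode = "excursion", norm = "hip_abduction")),
    SA = list(
      shoulder_abduction_left = list(
        series = angle_series(seq, tri("left_shoulder_long")),
        mode = "excursion", norm = "shoulder_abduction"),
      shoulder_abduction_right = list(
        series = angle_series(seq, tri("right_shoulder_long")),
        mode = "excursion", norm = "shoulder_abduction")),
    TR = list(
      lumbar_rotation = list(series = trunk_rotation_series(seq),
                             mode = "absolute", norm = "lumbar_rotation")),
    FB = list(
      spinal_flexion = list(series = trunk_flexion_series(seq),
                            mode = "absolute", norm = "spinal_flexion")),
    SQT = list(
      squat_hip_flexion_left = list(series = angle_series(seq, tri("left_hip")),
                                    mode = "excursion",
                                    norm = "squat_hip_flexion"),
      squat_knee_flexion_left = list(series = angle_series(seq, tri("left_knee")),
                                     mode = "excursion",
                                     norm = "squat_knee_flexion")),
    stop("unknown exercise: ", exercise)
  )
}

#' Analyse one exercise trial
#'
#' Full kinematic assessment of a trial with a known exercise label:
#' dominant-signal period and repetition segmentation (optionally after SSA
#' detrending for hand-held recordings), per-measure ROM with
#' median-of-maxima and normative ratio, angular velocity of the primary
#' measure, and guideline violations.
#'
#' @param seq a \code{pose_sequence} of one trial.
#' @param exercise exercise code (\code{"SS"}, \code{"SA"}, \code{"TR"},
#'   \code{"FB"}, \code{"SQT"}).
#' @param camera_fixed FALSE applies SSA detrending to the segmentation
#'   signal first (hand-held recording).
#' @param tolerance guideline tolerance (default 0.15).
#' @return A \code{trial_analysis}: \code{$period_s}, \code{$reps},
#'   \code{$rom} (per measure: \code{rom_summary}, normative comparison,
#'   \code{omega_rad_s}), \code{$violations}.
#' @export
analyze_trial <- function(seq, exercise, camera_fixed = TRUE,
                          tolerance = 0.15) {
  stopifnot(inherits(seq, "pose_sequence"))
  dom <- segmentation_signal(seq, exercise)
  if (!camera_fixed) dom <- detrend(dom, ssa_decompose(dom))
  period <- estimate_period(dom)
  reps <- segment_repetitions(dom, period)
  if (nrow(reps) == 0) stop("no repetitions found")
  measures <- exercise_measures(seq, exercise)
  M_sm <- max(1L, round(seq$fps / 30))   # ~3-sample jitter smoothing
  rom <- lapply(names(measures), function(nm) {
    m <- measures[[nm]]
    sm <- m$series
    sm$values <- moving_average(sm$values, M_sm, fs = seq$fps)$values
    rs <- rom_summary(sm, reps, mode = m$mode)
    if (exercise == "SS") {
      # alternating steps: summarise each hip over its own repetitions
      keep <- rs$per_rep_max >= 0.5 * max(rs$per_rep_max)
      if (any(keep))
        rs <- structure(list(per_rep_max = rs$per_rep_max[keep],
                             median_max = stats::median(rs$per_rep_max[keep]),
                             mode = rs$mode), class = "rom_summary")
    }
    cmp <- compare_to_normative(rs, m$norm)
    omega <- angular_velocity(deg2rad(rs$median_max),
                              stats::median(reps$duration))
    list(measure = nm, rom = rs, normative = cmp, omega_rad_s = omega)
  })
  names(rom) <- names(measures)
  viol <- check_guidelines(exercise, seq, reps, tolerance = tolerance,
                           period = period)
  structure(list(exercise = exercise, period_s = period, reps = reps,
                 rom = rom, violations = viol),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("<trial_analysis> %s: %d repetitions, period %.2f s\n",
              x$exercise, nrow(x$reps), x$period_s))
  for (r in x$rom)
    cat(sprintf("  %-26s median-of-maxima %6.1f deg (norm %3.0f, ratio %.2f), omega %.2f rad/s\n",
                r$measure, r$rom$median_max, r$normative$normative,
                r$normative$ratio, r$omega_rad_s))
  cat(sprintf("  violations: %d\n", nrow(x$violations)))
  invisible(x)
}

#' Export ROM and violation reports as CSV
#'
#' @param analysis a \code{trial_analysis}.
#' @param rom_path,violations_path output files (NULL skips).
#' @export
write_trial_report <- function(analysis, rom_path = NULL,
                               violations_path = NULL) {
  if (!is.null(rom_path)) {
    rows <- do.call(rbind, lapply(analysis$rom, function(r)
      data.frame(exercise = analysis$exercise, measure = r$measure,
                 per_rep_max = jsonlite::toJSON(r$rom$per_rep_max, digits = NA),
                 median_max_deg = r$rom$median_max,
                 normative_deg = r$normative$normative,
                 ratio = r$normative$ratio, omega_rad_s = r$omega_rad_s)))
    utils::write.csv(rows, rom_path, row.names = FALSE)
  }
  if (!is.null(violations_path))
    utils::write.csv(analysis$violations, violations_path, row.names = FALSE)
  invisible(analysis)
}
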