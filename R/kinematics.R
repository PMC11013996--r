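#' @title Joint-angle kinematics and ROM testing
#' @description
#' Joint angles by the cosine formula, angle time series with low-visibility
#' interpolation, per-repetition range of motion (ROM) with the
#' median-of-maxima summary, angular velocity, trunk rotation/flexion from
#' frontal-view foreshortening, movement coordination by cross-correlation,
#' and comparison against normative goniometer ROM values.
#' @name kinematics
NULL

#' Joint triplet
#'
#' Three landmark ids whose angle is measured at the middle vertex, plus the
#' coordinate plane to measure in.  The frontal \code{"xy"} plane is the
#' default everywhere because depth (z) estimates from monocular pose models
#' are unreliable.
#'
#' @param a,b,c distinct 0-based landmark ids; the angle sits at \code{b}.
#' @param plane \code{"xy"}, \code{"xz"} or \code{"xyz"}.
#' @export
joint_triplet <- function(a, b, c, plane = c("xy", "xz", "xyz")) {
  plane <- match.arg(plane)
  stopifnot(length(unique(c(a, b, c))) == 3L,
            all(c(a, b, c) >= 0), all(c(a, b, c) <= 32))
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 plane = plane), class = "joint_triplet")
}

#' Joint triplets used by the exercise repertoire
#' @keywords internal
JOINT_TRIPLETS <- list(
  left_elbow = c(11L, 13L, 15L), right_elbow = c(12L, 14L, 16L),
  left_knee = c(23L, 25L, 27L), right_knee = c(24L, 26L, 28L),
  left_hip = c(11L, 23L, 25L), right_hip = c(12L, 24L, 26L),
  left_shoulder = c(23L, 11L, 13L), right_shoulder = c(24L, 12L, 14L),
  # long-lever variants for ROM measurement: the distal endpoint doubles
  # the lever arm, halving the angular jitter of the pose estimates
  left_hip_long = c(11L, 23L, 27L), right_hip_long = c(12L, 24L, 28L),
  left_shoulder_long = c(23L, 11L, 15L), right_shoulder_long = c(24L, 12L, 16L)
)

plane_cols <- function(plane) {
  switch(plane, xy = c("x", "y"), xz = c("x", "z"), xyz = c("x", "y", "z"))
}

#' Angle at a vertex by the cosine formula
#'
#' \code{acos((a - b) . (c - b) / (|a - b| |c - b|))} in degrees, using only
#' the coordinates of the chosen plane.  Always in [0, 180].
#'
#' @param a,b,c numeric points (length >= the plane's dimension); the angle
#'   is measured at \code{b}.
#' @param plane coordinate plane, default \code{"xy"}.
#' @return Angle in degrees.
#' @export
joint_angle <- function(a, b, c, plane = "xy") {
  d <- length(plane_cols(plane))
  u <- a[seq_len(d)] - b[seq_len(d)]
  v <- c[seq_len(d)] - b[seq_len(d)]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= 1e-9 || nv <= 1e-9)
    stop("degenerate triplet: coincident points")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Joint-angle time series over a pose sequence
#'
#' Applies \code{\link{joint_angle}} per frame.  Frames where any of the
#' three landmarks falls below \code{vis_min} visibility are linearly
#' interpolated from their neighbours; if more than \code{max_missing} of
#' the frames are affected the series is rejected as unreliable.
#'
#' @param seq a \code{pose_sequence}.
#' @param joint a \code{joint_triplet}.
#' @param vis_min visibility threshold (default 0.5).
#' @param max_missing maximum tolerated fraction of low-visibility frames
#'   (default 0.1).
#' @return An \code{angle_series}: list with \code{$values} (degrees),
#'   \code{$fs}, \code{$joint}.
#' @export
angle_series <- function(seq, joint, vis_min = 0.5, max_missing = 0.1) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(joint, "joint_triplet"))
  n <- n_frames(seq)
  cols <- plane_cols(joint$plane)
  A <- seq$landmarks[, lm_row(joint$a), , drop = TRUE]
  B <- seq$landmarks[, lm_row(joint$b), , drop = TRUE]
  C <- seq$landmarks[, lm_row(joint$c), , drop = TRUE]
  if (n == 1) { A <- rbind(A); B <- rbind(B); C <- rbind(C) }
  colnames(A) <- colnames(B) <- colnames(C) <- FRAME_COLS
  ok <- A[, "v"] >= vis_min & B[, "v"] >= vis_min & C[, "v"] >= vis_min
  if (mean(!ok) > max_missing)
    stop("unreliable series: ", round(100 * mean(!ok)), "% low-visibility frames")
  vals <- rep(NA_real_, n)
  for (i in which(ok))
    vals[i] <- joint_angle(A[i, cols], B[i, cols], C[i, cols],
                           plane = joint$plane)
  if (anyNA(vals)) {
    if (sum(!is.na(vals)) < 2) stop("unreliable series: too few visible frames")
    vals <- stats::approx(which(!is.na(vals)), vals[!is.na(vals)],
                          xout = seq_len(n), rule = 2)$y
  }
  structure(list(values = vals, fs = seq$fps, joint = joint),
            class = "angle_series")
}

#' Per-repetition ROM and the median-of-maxima summary
#'
#' For each repetition segment the attained maximum is recorded and the
#' median over repetitions summarises the trial.  Two measurement
#' conventions are supported: \code{"excursion"} (abduction/rotation
#' measures) takes the angular span the joint sweeps away from its rest
#' posture within the segment; \code{"absolute"} (flexion measures, where
#' the series itself is already a flexion angle) takes the attained
#' maximum.  Extrema are read robustly at the \code{q}/\code{1 - q}
#' quantiles of the segment (default 2nd/98th percentile), so a
#' single-frame pose-estimation spike or a slightly misplaced segment
#' boundary cannot inflate or deflate a repetition's maximum; every
#' exercise profile rests at one extremum of its angle trace, making the
#' robust span equal to the attained excursion.
#'
#' @param angles an \code{angle_series} (or numeric vector of degrees +
#'   \code{fs}).
#' @param reps repetition data.frame from \code{\link{segment_repetitions}}
#'   (0-based half-open \code{start}/\code{end}).
#' @param mode \code{"excursion"} or \code{"absolute"}.
#' @param q tail fraction ignored when reading extrema (default 0.02).
#' @param fs sampling rate for bare vectors.
#' @return A \code{rom_summary}: list with \code{$per_rep_max} (degrees)
#'   and \code{$median_max}.
#' @export
rom_summary <- function(angles, reps, mode = c("excursion", "absolute"),
                        q = 0.02, fs = NULL) {
  mode <- match.arg(mode)
  x <- if (inherits(angles, "angle_series")) angles$values else sig_values(angles)
  if (is.null(reps) || nrow(reps) == 0) stop("empty repetition list")
  per_rep <- vapply(seq_len(nrow(reps)), function(i) {
    idx <- (reps$start[i] + 1L):min(reps$end[i], length(x))
    seg <- x[idx]
    hi <- stats::quantile(seg, 1 - q, names = FALSE, type = 7)
    lo <- stats::quantile(seg, q, names = FALSE, type = 7)
    if (mode == "excursion") hi - lo else hi
  }, numeric(1))
  structure(list(per_rep_max = per_rep, median_max = stats::median(per_rep),
                 mode = mode), class = "rom_summary")
}

#' Angular velocity of a repetition
#'
#' \code{omega = rom / duration}: the inscribed angle swept over the
#' duration of one repetition.
#'
#' @param rom inscribed angle in radians.
#' @param duration repetition duration in seconds (> 0).
#' @return Angular velocity in rad/s.
#' @export
angular_velocity <- function(rom, duration) {
  if (!is.numeric(duration) || any(duration <= 0))
    stop("duration must be positive")
  rom / duration
}

#' Degrees/radian helpers
#' @param deg,rad angles.
#' @export
deg2rad <- function(deg) deg * pi / 180
#' @rdname deg2rad
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Trunk rotation from shoulder-width foreshortening
#'
#' In a frontal view, rotating the trunk about the vertical axis shrinks
#' the apparent (image-plane) distance between the shoulders by the cosine
#' of the rotation: \code{theta = acos(apparent / calibrated)}.  The sign
#' comes from which shoulder moves toward the camera (smaller z) when depth
#' is trusted; the magnitude never relies on z.
#'
#' @param frame a \code{keypoint_frame}.
#' @param calib_shoulder_width shoulder width measured at neutral stance.
#' @param use_z take the rotation sign from the depth channel
#'   (default TRUE).
#' @return Rotation in degrees (signed when \code{use_z}).
#' @export
trunk_rotation_angle <- function(frame, calib_shoulder_width, use_z = TRUE) {
  frame <- as_frame(frame)
  if (!is.numeric(calib_shoulder_width) || calib_shoulder_width <= 0)
    stop("missing or invalid shoulder-width calibration")
  ls <- frame[lm_row(BLAZEPOSE[["left_shoulder"]]), ]
  rs <- frame[lm_row(BLAZEPOSE[["right_shoulder"]]), ]
  apparent <- abs(ls["x"] - rs["x"])
  theta <- acos(max(0, min(1, apparent / calib_shoulder_width))) * 180 / pi
  if (use_z) {
    s <- sign(rs["z"] - ls["z"])   # left shoulder closer => positive
    if (s != 0) theta <- s * theta
  }
  unname(theta)
}

#' Trunk forward flexion from apparent trunk shortening
#'
#' Pitching the trunk forward in a frontal view shortens the apparent
#' vertical pelvis-to-shoulder extent by the cosine of the flexion angle:
#' \code{theta = acos(apparent / calibrated)}.  A frontal-plane
#' approximation, used for the forward-bend ROM measure.
#'
#' @param frame a \code{keypoint_frame}.
#' @param calib_trunk_len vertical mid-hip to mid-shoulder extent at
#'   neutral stance.
#' @return Flexion in degrees (>= 0).
#' @export
trunk_flexion_angle <- function(frame, calib_trunk_len) {
  frame <- as_frame(frame)
  if (!is.numeric(calib_trunk_len) || calib_trunk_len <= 0)
    stop("missing or invalid trunk-length calibration")
  sy <- mean(frame[lm_row(BLAZEPOSE[c("left_shoulder", "right_shoulder")]), "y"])
  hy <- mean(frame[lm_row(BLAZEPOSE[c("left_hip", "right_hip")]), "y"])
  apparent <- hy - sy                      # y grows downwards
  acos(max(0, min(1, apparent / calib_trunk_len))) * 180 / pi
}

#' Movement coordination by cross-correlation
#'
#' Phase shifts among N body-part signals: \code{lag[i, j]} is the time (s)
#' by which part \code{j} trails part \code{i}, the argmax of their
#' normalized cross-correlation.  Parts are ranked into a participation
#' order by onset; the movement counts as unified when every pairwise lag
#' magnitude stays below \code{unify_threshold}.
#'
#' @param signals named list of \code{motion_signal}/\code{angle_series}
#'   (or numeric vectors), equal length and sampling rate.
#' @param unify_threshold lag threshold in seconds below which the parts
#'   move as one unit (default 0.15 x the common period if supplied,
#'   else 0.15 s).
#' @param period optional movement period in seconds for the default
#'   threshold.
#' @param fs sampling rate for bare vectors.
#' @return A \code{coordination_result}: \code{$lag_matrix} (s, antisymmetric,
#'   zero diagonal), \code{$order} (part names, first mover first),
#'   \code{$unified}.
#' @export
coordination <- function(signals, unify_threshold = NULL, period = NULL,
                         fs = NULL) {
  vals <- lapply(signals, function(s) {
    if (inherits(s, "angle_series")) s$values else sig_values(s)
  })
  fss <- vapply(signals, function(s) {
    if (inherits(s, c("motion_signal", "angle_series"))) s$fs else sig_fs(s, fs)
  }, numeric(1))
  if (length(unique(fss)) != 1L) stop("signals must share one sampling rate")
  fs <- fss[1]
  n <- length(vals[[1]])
  if (any(vapply(vals, length, 1L) != n)) stop("signals must have equal length")
  if (any(vapply(vals, stats::sd, 1) < 1e-12))
    stop("no phase information: constant series")
  if (is.null(unify_threshold))
    unify_threshold <- 0.15 * if (!is.null(period)) period else 1
  N <- length(vals)
  nm <- names(signals)
  if (is.null(nm)) nm <- paste0("part", seq_len(N))
  centered <- lapply(vals, function(v) v - mean(v))
  max_lag <- n - 2L
  lag_mat <- matrix(0, N, N, dimnames = list(nm, nm))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (j <= i) next
    cc <- stats::ccf(centered[[i]], centered[[j]], lag.max = max_lag,
                     plot = FALSE, demean = FALSE)
    k <- cc$lag[which.max(cc$acf), 1, 1]
    # ccf peaks at negative k when j trails i; store "j trails i" positive
    lag_mat[i, j] <- -k / fs
    lag_mat[j, i] <- k / fs
  }
  rel <- lag_mat[1, ]                       # trail times relative to part 1
  ord <- nm[order(rel)]
  off <- abs(lag_mat[upper.tri(lag_mat)])
  structure(list(parts = nm, lag_matrix = lag_mat, order = ord,
                 unified = all(off < unify_threshold),
                 unify_threshold = unify_threshold),
            class = "coordination_result")
}

# ---------------------------------------------------------------------------
# Normative ROM and execution-error guidelines
# ---------------------------------------------------------------------------

#' Normative ROM values (degrees)
#'
#' Goniometer reference values: AAOS norms for hip abduction (40),
#' shoulder abduction (180), lumbar rotation (45) and spinal forward
#' flexion (100); squat hip and knee flexion (95 and 85) after Hemmerich
#' et al.
#' @export
NORMATIVE_ROM <- c(
  hip_abduction = 40, shoulder_abduction = 180, lumbar_rotation = 45,
  spinal_flexion = 100, squat_hip_flexion = 95, squat_knee_flexion = 85
)

#' Compare a ROM summary to its normative value
#'
#' @param rom a \code{rom_summary} (or a single median-of-maxima value in
#'   degrees).
#' @param measure one of \code{names(NORMATIVE_ROM)}.
#' @param table normative table (default \code{NORMATIVE_ROM}).
#' @return List with \code{$ratio} (measured / normative), \code{$normative}
#'   and \code{$below_norm}.
#' @export
compare_to_normative <- function(rom, measure, table = NORMATIVE_ROM) {
  if (!measure %in% names(table)) stop("unknown ROM measure: ", measure)
  value <- if (inherits(rom, "rom_summary")) rom$median_max else as.numeric(rom)
  ratio <- value / table[[measure]]
  list(measure = measure, value = value, normative = table[[measure]],
       ratio = ratio, below_norm = ratio < 1)
}

guideline_violation <- function(exercise, rule, repetition, severity, message) {
  data.frame(exercise = exercise, rule = rule, repetition = repetition,
             severity = severity, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(exercise = character(0), rule = character(0),
             repetition = integer(0), severity = numeric(0),
             message = character(0), stringsAsFactors = FALSE)
}

rep_min <- function(values, reps, i) {
  idx <- (reps$start[i] + 1L):min(reps$end[i], length(values))
  min(values[idx])
}

#' Per-exercise execution-error checks
#'
#' Evaluates the repertoire's form guidelines per repetition with a relative
#' tolerance band (clamped to the 10--20\% margin used when scoring
#' repetitions as correct):
#' \itemize{
#'   \item SA: both elbows must stay extended -- minimum elbow angle at
#'     least \code{180 * (1 - tolerance)} degrees, else
#'     "Keep the arms straight!".
#'   \item TR: arms must stay perpendicular to the body axis (within
#'     \code{tolerance} of 90 degrees), and head/trunk/arms must not rotate
#'     as a single unit (coordination check).
#'   \item FB: legs must stay extended -- minimum knee angle at least
#'     \code{180 * (1 - tolerance)}, else "Keep the legs straight".
#'   \item SQT: knees must stay behind the toes -- knee landmark no more
#'     than \code{tolerance} of a foot length past the toe along the foot
#'     direction.
#'   \item SS/SA/TR upright-spine checks would need the sagittal (YZ)
#'     plane, which monocular depth cannot measure reliably, and are
#'     skipped.
#' }
#'
#' @param exercise one of \code{"SS"}, \code{"SA"}, \code{"TR"},
#'   \code{"FB"}, \code{"SQT"}.
#' @param seq the trial's \code{pose_sequence}.
#' @param reps repetition segments (data.frame from
#'   \code{\link{segment_repetitions}}).
#' @param tolerance relative deviation band, in [0.10, 0.20]
#'   (default 0.15).
#' @param period movement period in seconds (used by the TR coordination
#'   check).
#' @return data.frame of violations (possibly zero rows): exercise, rule,
#'   repetition (1-based, NA for trial-level rules), severity (relative
#'   deviation fraction) and feedback message.
#' @export
check_guidelines <- function(exercise, seq, reps, tolerance = 0.15,
                             period = NULL) {
  if (!exercise %in% names(EXERCISES)) stop("unknown exercise: ", exercise)
  if (tolerance < 0.10 || tolerance > 0.20)
    stop("tolerance must lie in [0.10, 0.20]")
  out <- no_violations()
  if (is.null(reps) || nrow(reps) == 0) return(out)
  tri <- function(nm) do.call(joint_triplet, as.list(JOINT_TRIPLETS[[nm]]))
  if (exercise == "SA") {
    el <- angle_series(seq, tri("left_elbow"))$values
    er <- angle_series(seq, tri("right_elbow"))$values
    thr <- 180 * (1 - tolerance)
    for (i in seq_len(nrow(reps))) {
      m <- min(rep_min(el, reps, i), rep_min(er, reps, i))
      if (m < thr)
        out <- rbind(out, guideline_violation("SA", "extended_arms", i,
                       (180 - m) / 180, "Keep the arms straight!"))
    }
  } else if (exercise == "FB") {
    kl <- angle_series(seq, tri("left_knee"))$values
    kr <- angle_series(seq, tri("right_knee"))$values
    thr <- 180 * (1 - tolerance)
    for (i in seq_len(nrow(reps))) {
      m <- min(rep_min(kl, reps, i), rep_min(kr, reps, i))
      if (m < thr)
        out <- rbind(out, guideline_violation("FB", "extended_legs", i,
                       (180 - m) / 180, "Keep the legs straight"))
    }
  } else if (exercise == "TR") {
    # arm-to-body-axis angle per side, lightly smoothed against pose jitter
    M <- max(1L, round(seq$fps / 10))
    al <- moving_average(arm_axis_angle(seq, "left"), M, fs = seq$fps)$values
    ar <- moving_average(arm_axis_angle(seq, "right"), M, fs = seq$fps)$values
    for (i in seq_len(nrow(reps))) {
      idx <- (reps$start[i] + 1L):min(reps$end[i], length(al))
      dev <- max(abs(c(al[idx], ar[idx]) - 90)) / 90
      if (dev > tolerance)
        out <- rbind(out, guideline_violation("TR", "arms_vertical_to_axis", i,
                       dev, "Keep arms vertical to the body axis"))
    }
    co <- tryCatch(tr_unified_check(seq, period), error = function(e) NULL)
    if (!is.null(co) && co$unified)
      out <- rbind(out, guideline_violation("TR", "unified_rotation", NA,
                     tolerance,
                     "Rotate the trunk, not the whole body as one unit"))
  } else if (exercise == "SQT") {
    lm <- seq$landmarks
    for (side in c("left", "right")) {
      knee <- lm[, lm_row(BLAZEPOSE[[paste0(side, "_knee")]]), "x"]
      toe <- lm[, lm_row(BLAZEPOSE[[paste0(side, "_foot_index")]]), "x"]
      heel <- lm[, lm_row(BLAZEPOSE[[paste0(side, "_heel")]]), "x"]
      fwd <- sign(stats::median(toe - heel))
      foot_len <- stats::median(abs(toe - heel))
      if (foot_len < 1e-6) next
      excess <- fwd * (knee - toe) / foot_len
      for (i in seq_len(nrow(reps))) {
        idx <- (reps$start[i] + 1L):min(reps$end[i], length(knee))
        sev <- max(excess[idx])
        if (sev > tolerance)
          out <- rbind(out, guideline_violation("SQT",
                         paste0("knees_behind_toes_", side), i, sev,
                         "Keep knees behind toes"))
      }
    }
  }
  # SS: frontal-plane spine check not measurable; step ROM handled elsewhere
  out
}

# angle between the upper arm and the body axis (mid-shoulder to mid-hip),
# image plane, per frame
arm_axis_angle <- function(seq, side) {
  lm <- seq$landmarks
  sh <- lm[, lm_row(BLAZEPOSE[[paste0(side, "_shoulder")]]), c("x", "y"), drop = TRUE]
  el <- lm[, lm_row(BLAZEPOSE[[paste0(side, "_elbow")]]), c("x", "y"), drop = TRUE]
  msx <- (lm[, lm_row(BLAZEPOSE[["left_shoulder"]]), "x"] +
            lm[, lm_row(BLAZEPOSE[["right_shoulder"]]), "x"]) / 2
  msy <- (lm[, lm_row(BLAZEPOSE[["left_shoulder"]]), "y"] +
            lm[, lm_row(BLAZEPOSE[["right_shoulder"]]), "y"]) / 2
  mhx <- (lm[, lm_row(BLAZEPOSE[["left_hip"]]), "x"] +
            lm[, lm_row(BLAZEPOSE[["right_hip"]]), "x"]) / 2
  mhy <- (lm[, lm_row(BLAZEPOSE[["left_hip"]]), "y"] +
            lm[, lm_row(BLAZEPOSE[["right_hip"]]), "y"]) / 2
  if (is.null(dim(sh))) { sh <- rbind(sh); el <- rbind(el) }
  ux <- el[, 1] - sh[, 1]; uy <- el[, 2] - sh[, 2]
  vx <- mhx - msx; vy <- mhy - msy
  cosang <- (ux * vx + uy * vy) /
    pmax(sqrt(ux^2 + uy^2) * sqrt(vx^2 + vy^2), 1e-12)
  acos(pmax(-1, pmin(1, cosang))) * 180 / pi
}

# trunk vs arm rotation-proxy coordination for the TR unified-movement check
tr_unified_check <- function(seq, period = NULL) {
  lm <- seq$landmarks
  trunk <- abs(lm[, lm_row(BLAZEPOSE[["left_shoulder"]]), "x"] -
                 lm[, lm_row(BLAZEPOSE[["right_shoulder"]]), "x"])
  # wrist spread with the shoulder contribution removed: pure arm azimuth
  arms <- abs(lm[, lm_row(BLAZEPOSE[["left_wrist"]]), "x"] -
                lm[, lm_row(BLAZEPOSE[["right_wrist"]]), "x"]) - trunk
  thr <- if (!is.null(period)) 0.15 * period else NULL
  coordination(list(trunk = motion_signal(trunk, seq$fps),
                    arms = motion_signal(arms, seq$fps)),
               unify_threshold = thr, period = period)
}
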