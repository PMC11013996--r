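#' @title Synthetic skeleton-motion generator
#' @description
#' Parametric generator of 33-landmark keypoint sequences for the five
#' exercises, with ground-truth labels, ROM, periods, repetition boundaries,
#' pauses, hand-held-camera drift and injectable execution errors.  Motion
#' is planar (frontal-view) forward kinematics from the pelvis with a small
#' synthetic depth channel for trunk rotation; joint-angle profiles are
#' raised cosines, \code{theta(t) = rom * (1 - cos(2 pi t / period)) / 2},
#' which are C1-smooth and return to the rest posture at every repetition
#' boundary.
#' @name synthetic_motion
NULL

#' Skeleton segment lengths (normalized image units)
#'
#' Default proportions place a standing adult figure inside the unit image
#' with margin; \code{arm_len = upper_arm + forearm_hand} is the
#' shoulder-to-index-tip distance that the reference-distance calibration
#' measures.
#'
#' @param trunk,head,shoulder_width,hip_width,upper_arm,forearm_hand,thigh,shank,foot_len
#'   segment lengths.
#' @param pelvis_x,pelvis_y neutral stance pelvis position.
#' @export
skeleton_spec <- function(trunk = 0.22, head = 0.08, shoulder_width = 0.16,
                          hip_width = 0.09, upper_arm = 0.11,
                          forearm_hand = 0.14, thigh = 0.16, shank = 0.15,
                          foot_len = 0.05, pelvis_x = 0.5, pelvis_y = 0.60) {
  s <- list(trunk = trunk, head = head, shoulder_width = shoulder_width,
            hip_width = hip_width, upper_arm = upper_arm,
            forearm_hand = forearm_hand, thigh = thigh, shank = shank,
            foot_len = foot_len, pelvis_x = pelvis_x, pelvis_y = pelvis_y)
  stopifnot(all(vapply(s[1:9], function(v) v > 0, logical(1))))
  structure(s, class = "skeleton_spec")
}

#' One phase of a motion script
#'
#' @param exercise \code{"SS"}, \code{"SA"}, \code{"TR"}, \code{"FB"},
#'   \code{"SQT"} or \code{"idle"}.
#' @param rom_deg driven range of motion in degrees (primary measure of the
#'   exercise).
#' @param period_s repetition period in seconds.
#' @param n_reps number of repetitions (>= 1 for exercises).
#' @param pause_after_s standing pause appended after the phase.
#' @param duration_s duration for \code{"idle"} phases.
#' @param errors character vector of injected execution errors, from
#'   \code{"bent_elbow"}, \code{"bent_knee"}, \code{"knees_past_toes"},
#'   \code{"unified_trunk_rotation"}, \code{"partial_body"}.
#' @param bent_elbow_deg,bent_knee_deg error magnitudes in degrees.
#' @export
motion_phase <- function(exercise, rom_deg = 45, period_s = 2, n_reps = 5,
                         pause_after_s = 0, duration_s = NULL,
                         errors = character(0), bent_elbow_deg = 40,
                         bent_knee_deg = 40) {
  stopifnot(exercise %in% c(names(EXERCISES), "idle"))
  if (exercise != "idle") stopifnot(rom_deg > 0, period_s > 0, n_reps >= 1)
  list(exercise = exercise, rom_deg = rom_deg, period_s = period_s,
       n_reps = n_reps, pause_after_s = pause_after_s,
       duration_s = duration_s, errors = errors,
       bent_elbow_deg = bent_elbow_deg, bent_knee_deg = bent_knee_deg)
}

#' A motion script: ordered phases plus recording conditions
#'
#' @param phases list of \code{\link{motion_phase}}.
#' @param fps frames per second (default 30, the web-camera rate).
#' @param noise_sd i.i.d. Gaussian landmark noise, normalized units
#'   (default 0.003, mimicking pose-model jitter).
#' @param drift_sd per-frame step of the common-mode random-walk camera
#'   drift (default 0: fixed camera).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @export
motion_script <- function(phases, fps = 30, noise_sd = 0.003, drift_sd = 0,
                          seed = 1) {
  stopifnot(length(phases) >= 1, fps > 0)
  structure(list(phases = phases, fps = fps, noise_sd = noise_sd,
                 drift_sd = drift_sd, seed = seed), class = "motion_script")
}

rot2 <- function(x, y, a) list(x = x * cos(a) - y * sin(a),
                               y = x * sin(a) + y * cos(a))

# frame-parameter drive for one exercise phase; all angles in radians,
# vectors over the phase's frames
phase_drive <- function(phase, fps) {
  if (phase$exercise == "idle") {
    n <- max(1L, round(phase$duration_s * fps))
    return(list(n = n, theta = numeric(n), rep_of = integer(n)))
  }
  P <- phase$period_s
  n <- round(phase$n_reps * P * fps)
  t <- (seq_len(n) - 1) / fps
  theta <- deg2rad(phase$rom_deg) * (1 - cos(2 * pi * t / P)) / 2
  list(n = n, t = t, theta = theta,
       rep_of = pmin(phase$n_reps, floor(t / P) + 1L),
       rep_frames = round((0:phase$n_reps) * P * fps))
}

#' Simulate a scripted keypoint sequence
#'
#' Drives the relevant joint angles per phase and maps them onto the 33
#' landmarks by planar forward kinematics: SS = alternating hip
#' ab/adduction (left leg on odd repetitions); SA = bilateral shoulder
#' abduction with extended elbows; TR = trunk rotation rendered as
#' shoulder-width foreshortening with a signed depth offset, arms held at
#' 90 degrees abduction and trailing the trunk by 0.2 periods (rotating as
#' one unit under the \code{unified_trunk_rotation} error); FB = trunk
#' forward flexion rendered as trunk foreshortening; SQT = coupled hip and
#' knee flexion building the legs up from fixed ankles.  Adds i.i.d.
#' Gaussian landmark noise and an optional shared random-walk camera drift;
#' visibility is 1 except under the \code{partial_body} error, which pushes
#' the lower body out of frame.
#'
#' @param script a \code{\link{motion_script}}.
#' @param skeleton a \code{\link{skeleton_spec}}.
#' @return List: \code{$seq} (the noisy \code{pose_sequence}) and
#'   \code{$truth} (per-phase label, frame range, repetition boundaries,
#'   true ROM per measure, true period, injected errors, plus the clean
#'   pre-noise landmark array in \code{$clean}).
#' @export
simulate_motion <- function(script, skeleton = skeleton_spec()) {
  stopifnot(inherits(script, "motion_script"))
  sk <- skeleton
  fps <- script$fps
  drives <- lapply(script$phases, phase_drive, fps = fps)
  blocks <- list(); truth_phases <- list(); offset <- 0L
  for (pi in seq_along(script$phases)) {
    ph <- script$phases[[pi]]
    d <- drives[[pi]]
    blk <- build_phase_frames(ph, d, sk, fps)
    n_pause <- round(ph$pause_after_s * fps)
    if (n_pause > 0) {
      neutral <- build_phase_frames(motion_phase("idle", duration_s = n_pause / fps),
                                    phase_drive(motion_phase("idle",
                                      duration_s = n_pause / fps), fps), sk, fps)
      blk <- abind3(blk, neutral)
    }
    truth_phases[[pi]] <- list(
      exercise = ph$exercise,
      start_frame = offset, end_frame = offset + d$n,   # 0-based half-open
      rep_boundaries = if (!is.null(d$rep_frames)) offset + d$rep_frames else integer(0),
      rom = phase_true_rom(ph),
      period = if (ph$exercise == "idle") NA_real_ else ph$period_s,
      n_reps = if (ph$exercise == "idle") 0L else ph$n_reps,
      errors = ph$errors
    )
    blocks[[pi]] <- blk
    offset <- offset + dim(blk)[1]
  }
  clean <- do.call(abind3, blocks)
  n <- dim(clean)[1]
  set.seed(script$seed)
  noisy <- clean
  if (script$drift_sd > 0) {
    dx <- cumsum(stats::rnorm(n, 0, script$drift_sd))
    dy <- cumsum(stats::rnorm(n, 0, script$drift_sd))
    noisy[, , "x"] <- noisy[, , "x"] + dx
    noisy[, , "y"] <- noisy[, , "y"] + dy
  }
  if (script$noise_sd > 0) {
    for (ax in AXES)
      noisy[, , ax] <- noisy[, , ax] +
        stats::rnorm(n * N_LANDMARKS, 0, script$noise_sd)
  }
  out_of_frame <- any(clean[, , "x"] < 0 | clean[, , "x"] > 1 |
                        clean[, , "y"] < 0 | clean[, , "y"] > 1)
  has_partial <- any(vapply(script$phases,
                            function(p) "partial_body" %in% p$errors, logical(1)))
  seq <- pose_sequence(noisy, fps = fps,
                       meta = list(source = "synthetic",
                                   seed = script$seed))
  list(seq = seq,
       truth = list(phases = truth_phases, clean = clean, fps = fps,
                    out_of_frame_warning = out_of_frame && !has_partial))
}

abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, N_LANDMARKS, 4L),
               dimnames = list(NULL, NULL, FRAME_COLS))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

phase_true_rom <- function(ph) {
  if (ph$exercise == "idle") return(numeric(0))
  switch(ph$exercise,
    SS = c(hip_abduction = ph$rom_deg),
    SA = c(shoulder_abduction = ph$rom_deg),
    TR = c(lumbar_rotation = ph$rom_deg),
    FB = c(spinal_flexion = ph$rom_deg),
    SQT = c(squat_hip_flexion = ph$rom_deg,
            squat_knee_flexion = ph$rom_deg +
              rad2deg(pmin(0.25 * deg2rad(ph$rom_deg), deg2rad(10))))
  )
}

# planar forward kinematics for one phase: returns n x 33 x 4 clean array
build_phase_frames <- function(ph, d, sk, fps) {
  n <- d$n
  theta <- d$theta
  z <- numeric(n)
  # driven parameters, all length n, radians
  arm_abd_l <- arm_abd_r <- numeric(n)
  arm_azim_l <- arm_azim_r <- numeric(n)
  elbow_flex <- numeric(n)
  hip_abd_l <- hip_abd_r <- numeric(n)
  knee_flex <- numeric(n)
  trunk_flex <- numeric(n)
  trunk_rot <- numeric(n)
  squat <- FALSE
  shank_lean <- numeric(n)
  ex <- ph$exercise
  if (ex == "SS") {
    odd <- d$rep_of %% 2L == 1L
    hip_abd_l[odd] <- theta[odd]
    hip_abd_r[!odd] <- theta[!odd]
  } else if (ex == "SA") {
    arm_abd_l <- arm_abd_r <- theta
    if ("bent_elbow" %in% ph$errors)
      elbow_flex <- deg2rad(ph$bent_elbow_deg) * (1 - cos(2 * pi * d$t / ph$period_s)) / 2
  } else if (ex == "TR") {
    sgn <- ifelse(d$rep_of %% 2L == 1L, 1, -1)
    trunk_rot <- sgn * theta
    arm_abd_l <- arm_abd_r <- rep(pi / 2, n)
    if ("unified_trunk_rotation" %in% ph$errors) {
      arm_azim_l <- arm_azim_r <- trunk_rot
    } else {
      lag <- round(0.2 * ph$period_s * fps)
      lagged <- c(numeric(lag), trunk_rot)[seq_len(n)]
      arm_azim_l <- arm_azim_r <- lagged
    }
  } else if (ex == "FB") {
    trunk_flex <- theta
    if ("bent_knee" %in% ph$errors)
      knee_flex <- deg2rad(ph$bent_knee_deg) * (1 - cos(2 * pi * d$t / ph$period_s)) / 2
  } else if (ex == "SQT") {
    squat <- TRUE
    lean_cap <- if ("knees_past_toes" %in% ph$errors) deg2rad(50) else deg2rad(10)
    lean_gain <- if ("knees_past_toes" %in% ph$errors) 0.6 else 0.25
    shank_lean <- pmin(lean_gain * theta, lean_cap)
  }

  px <- rep(sk$pelvis_x, n); py <- rep(sk$pelvis_y, n)
  P <- array(0, dim = c(n, N_LANDMARKS, 4L),
             dimnames = list(NULL, NULL, FRAME_COLS))
  P[, , "v"] <- 1
  set_lm <- function(id, x, y, zz = NULL) {
    r <- lm_row(id)
    P[, r, "x"] <<- x; P[, r, "y"] <<- y
    if (!is.null(zz)) P[, r, "z"] <<- zz
  }

  # --- legs (squats drive pelvis height; legs fold outward in-plane) ----
  if (squat) py <- py + sk$thigh * (1 - cos(theta)) +
    sk$shank * (1 - cos(shank_lean))
  leg <- function(s, hip_abd) {
    if (squat) {
      hx <- px + s * sk$hip_width / 2
      hy <- py
      kx <- hx + s * sk$thigh * sin(theta)       # thigh folds outward
      ky <- hy + sk$thigh * cos(theta)
      ax <- kx - s * sk$shank * sin(shank_lean)  # shank leans back inward
      ay <- ky + sk$shank * cos(shank_lean)
      list(hip = list(x = hx, y = hy), knee = list(x = kx, y = ky),
           ankle = list(x = ax, y = ay),
           knee_z = -0.3 * sk$shank * sin(shank_lean))
    } else {
      hx <- px + s * sk$hip_width / 2
      hy <- py
      ux <- s * sin(hip_abd); uy <- cos(hip_abd)
      kx <- hx + sk$thigh * ux; ky <- hy + sk$thigh * uy
      sb <- rot2(ux, uy, -s * knee_flex)    # shank bends toward midline
      axp <- kx + sk$shank * sb$x; ayp <- ky + sk$shank * sb$y
      list(hip = list(x = hx, y = hy), knee = list(x = kx, y = ky),
           ankle = list(x = axp, y = ayp), knee_z = numeric(n))
    }
  }
  L <- leg(+1, hip_abd_l); R <- leg(-1, hip_abd_r)
  if (squat) { px <- (L$hip$x + R$hip$x) / 2; py <- (L$hip$y + R$hip$y) / 2 }

  set_lm(BLAZEPOSE[["left_hip"]], L$hip$x, L$hip$y)
  set_lm(BLAZEPOSE[["right_hip"]], R$hip$x, R$hip$y)
  set_lm(BLAZEPOSE[["left_knee"]], L$knee$x, L$knee$y, L$knee_z)
  set_lm(BLAZEPOSE[["right_knee"]], R$knee$x, R$knee$y, R$knee_z)
  set_lm(BLAZEPOSE[["left_ankle"]], L$ankle$x, L$ankle$y)
  set_lm(BLAZEPOSE[["right_ankle"]], R$ankle$x, R$ankle$y)
  foot <- function(side, s) {
    a <- if (side == "l") L$ankle else R$ankle
    set_lm(BLAZEPOSE[[paste0(ifelse(side == "l", "left", "right"), "_heel")]],
           a$x - s * 0.01, a$y + 0.02)
    set_lm(BLAZEPOSE[[paste0(ifelse(side == "l", "left", "right"),
                             "_foot_index")]],
           a$x - s * 0.01 + s * sk$foot_len, a$y + 0.02)
  }
  foot("l", +1); foot("r", -1)

  # --- trunk, head ------------------------------------------------------
  scx <- px
  scy <- py - sk$trunk * cos(trunk_flex)
  cw <- cos(trunk_rot); swid <- sk$shoulder_width / 2
  slx <- scx + swid * cw; srx <- scx - swid * cw
  slz <- -swid * sin(trunk_rot); srz <- +swid * sin(trunk_rot)
  set_lm(BLAZEPOSE[["left_shoulder"]], slx, scy, slz)
  set_lm(BLAZEPOSE[["right_shoulder"]], srx, scy, srz)
  nx <- scx; ny <- scy - sk$head * cos(trunk_flex)
  set_lm(BLAZEPOSE[["nose"]], nx, ny)
  face <- list(left_eye_inner = c(+0.010, -0.012), left_eye = c(+0.016, -0.012),
               left_eye_outer = c(+0.022, -0.012),
               right_eye_inner = c(-0.010, -0.012), right_eye = c(-0.016, -0.012),
               right_eye_outer = c(-0.022, -0.012),
               left_ear = c(+0.030, -0.006), right_ear = c(-0.030, -0.006),
               mouth_left = c(+0.010, +0.012), mouth_right = c(-0.010, +0.012))
  for (nm in names(face)) {
    off <- face[[nm]]
    set_lm(BLAZEPOSE[[nm]], nx + off[1] * cw, ny + off[2],
           -off[1] * sin(trunk_rot))
  }

  # --- arms -------------------------------------------------------------
  arm <- function(s, abd, azim, shx, shy, shz) {
    ux <- s * sin(abd) * cos(azim)
    uy <- cos(abd)
    uz <- -s * sin(abd) * sin(azim)   # same depth sense as the shoulders
    ex_ <- shx + sk$upper_arm * ux
    ey_ <- shy + sk$upper_arm * uy
    ez_ <- shz + sk$upper_arm * uz
    fb <- rot2(ux, uy, -s * elbow_flex)      # forearm bends toward midline
    hand <- sk$forearm_hand
    wrist_frac <- 0.11 / 0.14                # wrist sits before the index tip
    wx <- ex_ + hand * wrist_frac * fb$x; wy <- ey_ + hand * wrist_frac * fb$y
    wz <- ez_ + hand * wrist_frac * uz
    ix <- ex_ + hand * fb$x; iy <- ey_ + hand * fb$y; iz <- ez_ + hand * uz
    list(elbow = c3(ex_, ey_, ez_), wrist = c3(wx, wy, wz),
         index = c3(ix, iy, iz),
         pinky = c3(ix - s * 0.008, iy, iz), thumb = c3(wx + s * 0.010, wy, wz))
  }
  c3 <- function(x, y, z) list(x = x, y = y, z = z)
  AL <- arm(+1, arm_abd_l, arm_azim_l, slx, scy, slz)
  AR <- arm(-1, arm_abd_r, arm_azim_r, srx, scy, srz)
  for (side in c("left", "right")) {
    A <- if (side == "left") AL else AR
    set_lm(BLAZEPOSE[[paste0(side, "_elbow")]], A$elbow$x, A$elbow$y, A$elbow$z)
    set_lm(BLAZEPOSE[[paste0(side, "_wrist")]], A$wrist$x, A$wrist$y, A$wrist$z)
    set_lm(BLAZEPOSE[[paste0(side, "_index")]], A$index$x, A$index$y, A$index$z)
    set_lm(BLAZEPOSE[[paste0(side, "_pinky")]], A$pinky$x, A$pinky$y, A$pinky$z)
    set_lm(BLAZEPOSE[[paste0(side, "_thumb")]], A$thumb$x, A$thumb$y, A$thumb$z)
  }

  if ("partial_body" %in% ph$errors) {
    lower <- lm_row(unname(BLAZEPOSE[c("left_knee", "right_knee", "left_ankle",
                                       "right_ankle", "left_heel", "right_heel",
                                       "left_foot_index", "right_foot_index")]))
    P[, lower, "y"] <- 1.05
    P[, lower, "v"] <- 0.1
  }
  P
}

#' Canned real-time testing scenario
#'
#' The demonstration session: idle start, two clean side-step repetitions,
#' a pause, shoulder abductions with excessively bent elbows, then clean
#' shoulder abductions.
#'
#' @param fps frames per second.
#' @param noise_sd landmark noise.
#' @param seed RNG seed.
#' @return A \code{\link{motion_script}}.
#' @export
scenario_script <- function(fps = 30, noise_sd = 0.002, seed = 1) {
  motion_script(list(
    motion_phase("idle", duration_s = 6),
    motion_phase("SS", rom_deg = 40, period_s = 2, n_reps = 2,
                 pause_after_s = 6),
    motion_phase("SA", rom_deg = 150, period_s = 2.5, n_reps = 3,
                 errors = "bent_elbow", bent_elbow_deg = 40),
    motion_phase("SA", rom_deg = 150, period_s = 2.5, n_reps = 3)
  ), fps = fps, noise_sd = noise_sd, seed = seed)
}

#' Class templates for the default synthetic corpus
#' @keywords internal
EXERCISE_TEMPLATES <- list(
  SS = list(rom_deg = 40, period_s = 2.0),
  SA = list(rom_deg = 150, period_s = 2.5),
  TR = list(rom_deg = 45, period_s = 3.0),
  FB = list(rom_deg = 45, period_s = 3.0),
  SQT = list(rom_deg = 80, period_s = 2.5)
)

#' Generate a labelled multi-subject corpus
#'
#' Per subject, skeleton proportions and per-exercise ROM / period are
#' jittered around the class templates (normal jitter, ROM 10\% and period
#' 15\% by default) and one trial per exercise is simulated.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param reps_per_exercise repetitions per trial (default 6).
#' @param rom_jitter,period_jitter relative s.d. of the per-subject jitter.
#' @param noise_sd landmark noise (default 0.003).
#' @param fps frames per second.
#' @param seed RNG seed.
#' @return List of trials; each trial has \code{$seq}, \code{$truth},
#'   \code{$subject}, \code{$exercise}.
#' @export
make_dataset <- function(n_subjects, reps_per_exercise = 6,
                         rom_jitter = 0.10, period_jitter = 0.15,
                         noise_sd = 0.003, fps = 30, seed = 1) {
  stopifnot(n_subjects >= 2)
  set.seed(seed)
  trials <- list()
  for (s in seq_len(n_subjects)) {
    scale <- 1 + stats::rnorm(1, 0, 0.05)
    sk <- skeleton_spec(trunk = 0.22 * scale, head = 0.08 * scale,
                        shoulder_width = 0.16 * scale,
                        hip_width = 0.09 * scale, upper_arm = 0.11 * scale,
                        forearm_hand = 0.14 * scale, thigh = 0.16 * scale,
                        shank = 0.15 * scale, foot_len = 0.05 * scale)
    for (ex in names(EXERCISES)) {
      tpl <- EXERCISE_TEMPLATES[[ex]]
      rom <- tpl$rom_deg * (1 + stats::rnorm(1, 0, rom_jitter))
      per <- tpl$period_s * (1 + stats::rnorm(1, 0, period_jitter))
      rom <- max(5, min(rom, if (ex == "SA") 175 else 120))
      per <- max(1, per)
      trial_seed <- seed * 10000L + s * 100L + EXERCISES[[ex]]
      scr <- motion_script(list(
        motion_phase(ex, rom_deg = rom, period_s = per,
                     n_reps = reps_per_exercise)
      ), fps = fps, noise_sd = noise_sd, seed = trial_seed)
      sim <- simulate_motion(scr, sk)
      trials[[length(trials) + 1L]] <-
        list(seq = sim$seq, truth = sim$truth, subject = s, exercise = ex)
    }
  }
  trials
}

#' Per-repetition feature table of a corpus
#'
#' Runs each trial through the standard chain -- 99 signals, basic-keypoint
#' selection, repetition segmentation on the dominant (maximum-variance)
#' basic signal, 285 features per repetition.  With
#' \code{method = "truth"} the generator's ground-truth repetition
#' boundaries are used instead of the estimated ones.
#'
#' @param trials corpus from \code{\link{make_dataset}}.
#' @param method \code{"pipeline"} (estimate period and segment) or
#'   \code{"truth"}.
#' @return List with \code{$X} (matrix, 285 columns), \code{$y} (exercise
#'   labels), \code{$subjects}.
#' @export
corpus_features <- function(trials, method = c("pipeline", "truth")) {
  method <- match.arg(method)
  rows <- list(); labs <- character(0); subs <- integer(0)
  for (tr in trials) {
    ss <- extract_signals(tr$seq)
    basic <- select_basic_signals(ss)
    reps <- NULL
    if (method == "pipeline") {
      dom <- segmentation_signal(basic, tr$exercise)
      reps <- tryCatch({
        per <- estimate_period(dom)
        segment_repetitions(dom, per)
      }, error = function(e) NULL)
    }
    if (is.null(reps) || nrow(reps) == 0) {
      b <- tr$truth$phases[[1]]$rep_boundaries
      reps <- data.frame(start = b[-length(b)], end = b[-1],
                         duration = diff(b) / tr$seq$fps)
    }
    for (i in seq_len(nrow(reps))) {
      idx <- (reps$start[i] + 1L):min(reps$end[i], n_frames(tr$seq))
      if (length(idx) < 8) next
      win <- lapply(basic, function(s)
        motion_signal(s$values[idx], s$fs, label = s$label))
      rows[[length(rows) + 1L]] <- extract_features(win)
      labs <- c(labs, tr$exercise)
      subs <- c(subs, tr$subject)
    }
  }
  X <- do.call(rbind, rows)
  list(X = X, y = labs, subjects = subs)
}
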