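#' @title Real-time feedback session engine
#' @description
#' A headless state machine that consumes keypoint frames and emits
#' feedback messages: full-body check and calibration, inactivity
#' motivation, exercise recognition, repetition counting, exercise-change
#' detection and execution-error corrections.  The engine never touches
#' video or rendering; any overlay is an adapter on top of the emitted
#' messages, which keeps the core deterministic and testable.
#' @name session_engine
NULL

#' Session engine configuration
#'
#' @param vis_min visibility threshold for the full-body check.
#' @param calib_window seconds of continuous full-body visibility required
#'   before calibration.
#' @param idle_timeout seconds of inactivity between motivation messages.
#' @param pause_timeout seconds of inactivity that suspends tracking.
#' @param change_votes consecutive disagreeing predictions required before
#'   an exercise switch is accepted.
#' @param eval_interval seconds between heavy evaluations of the buffer.
#' @param recog_fallback_s recognition window when period estimation fails.
#' @param tolerance guideline tolerance band (0.10--0.20).
#' @param max_window_s cap on the analysis window length.
#' @export
session_config <- function(vis_min = 0.5, calib_window = 1, idle_timeout = 5,
                           pause_timeout = 3, change_votes = 2,
                           eval_interval = 0.5, recog_fallback_s = 3,
                           tolerance = 0.15, max_window_s = 30) {
  as.list(environment())
}

SESSION_MODES <- c("WAIT_FULL_BODY", "CALIBRATING", "IDLE", "RECOGNIZING",
                   "TRACKING")

#' Create a fresh session state
#'
#' @param model a \code{kinerehab_model} bundle (from
#'   \code{\link{train_and_evaluate}}), used for exercise recognition;
#'   may be NULL for engines that only count and check a preset exercise.
#' @param config a \code{\link{session_config}}.
#' @return A \code{session_state} (mode \code{WAIT_FULL_BODY}).
#' @export
new_session <- function(model = NULL, config = session_config()) {
  structure(list(
    mode = "WAIT_FULL_BODY", config = config, model = model,
    frames = list(), t = numeric(0), fps = NA_real_,
    crop = NULL, vis_streak_start = NA_real_, invis_since = NA_real_,
    current_exercise = NULL, rep_count = 0L, base_count = 0L,
    period = NA_real_, activity_start = NA_integer_,
    last_prompt = -Inf, last_motivation = -Inf, last_eval = -Inf,
    last_pred = NULL, change_streak = 0L, latched = character(0),
    clean_streak = 0L, log = list()
  ), class = "session_state")
}

msg <- function(kind, text, t) list(kind = kind, text = text, t = t)

log_event <- function(state, type, t, payload = NULL) {
  state$log[[length(state$log) + 1L]] <-
    list(t = t, type = type, payload = payload)
  state
}

window_seq <- function(state, from, to = length(state$frames)) {
  pose_sequence(state$frames[from:to], fps = state$fps,
                t = state$t[from:to] - state$t[from])
}

# segmentation driver over a frame range (exercise-aware once recognized)
dominant_signal <- function(state, from, to = length(state$frames),
                            exercise = NULL) {
  segmentation_signal(window_seq(state, from, to), exercise)
}

window_active <- function(state, from, to = length(state$frames),
                          exercise = NULL) {
  if (to - from < 5) return(FALSE)
  dom <- dominant_signal(state, from, to, exercise)
  seg <- detect_activity(dom)
  tail_kind <- seg$kind[nrow(seg)]
  tail_kind == "active"
}

# seconds of inactivity at the end of the window (0 when currently active)
trailing_pause_s <- function(state, from, to = length(state$frames),
                             exercise = NULL) {
  if (to - from < 5) return(0)
  dom <- dominant_signal(state, from, to, exercise)
  seg <- detect_activity(dom)
  last <- nrow(seg)
  if (seg$kind[last] != "pause") return(0)
  (seg$end[last] - seg$start[last]) / state$fps
}

#' Advance the session by one keypoint frame
#'
#' Implements the transition graph: \code{WAIT_FULL_BODY} prompts the user
#' to step back until the whole body has been visible for the calibration
#' window, then calibrates the crop box and enters \code{IDLE}; activity
#' moves \code{IDLE} to \code{RECOGNIZING}, inactivity triggers periodic
#' motivation; once the buffer spans an execution period the exercise is
#' predicted and \code{TRACKING} counts repetitions, checks guidelines and
#' repeats corrections until the violation clears; sustained inactivity
#' falls back to \code{IDLE} (counter retained) and a changed prediction on
#' consecutive windows resets the counter and announces the new exercise.
#'
#' @param state a \code{session_state}.
#' @param frame a \code{keypoint_frame} (33 x 4 matrix); attribute \code{t}
#'   or \code{t} argument gives its timestamp.
#' @param t frame timestamp in seconds.
#' @return List \code{$state}, \code{$messages} (possibly empty list of
#'   \code{kind}/\code{text}/\code{t}).
#' @export
step <- function(state, frame, t = attr(frame, "t")) {
  cfg <- state$config
  out <- list()
  frame <- as_frame(frame)
  k <- length(state$frames) + 1L
  state$frames[[k]] <- unclass(frame)
  state$t[k] <- t
  if (is.na(state$fps) && k >= 2)
    state$fps <- 1 / stats::median(diff(state$t))
  # trim the rolling buffer
  if (k > 3 && !is.na(state$fps) &&
      (state$t[k] - state$t[1]) > 2 * cfg$max_window_s) {
    drop <- which(state$t < state$t[k] - cfg$max_window_s)
    if (length(drop)) {
      state$frames <- state$frames[-drop]
      state$t <- state$t[-drop]
      state$activity_start <-
        if (!is.na(state$activity_start)) max(1L, state$activity_start - length(drop))
        else NA_integer_
      k <- length(state$frames)
    }
  }

  emit <- function(kind, text) {
    out[[length(out) + 1L]] <<- msg(kind, text, t)
    state <<- log_event(state, "message", t,
                        list(kind = kind, text = text))
  }
  transition <- function(mode) {
    state <<- log_event(state, "transition", t,
                        list(from = state$mode, to = mode))
    state$mode <<- mode
  }

  if (state$mode == "WAIT_FULL_BODY") {
    visible <- full_body_visible(frame, cfg$vis_min)
    if (!visible) {
      state$vis_streak_start <- NA_real_
      if (t - state$last_prompt >= 2) {
        emit("prompt", "Step back until your entire body is visible")
        state$last_prompt <- t
      }
    } else {
      if (is.infinite(state$last_prompt)) {
        emit("prompt", "Step back until your entire body is visible")
        state$last_prompt <- t
      }
      if (is.na(state$vis_streak_start)) state$vis_streak_start <- t
      if (t - state$vis_streak_start >= cfg$calib_window && !is.na(state$fps)) {
        transition("CALIBRATING")
        vis_idx <- which(state$t >= state$vis_streak_start)
        state$crop <- tryCatch(
          compute_crop_box(window_seq(state, vis_idx[1]),
                           calib_window = cfg$calib_window,
                           vis_min = cfg$vis_min),
          error = function(e) NULL)
        state <- log_event(state, "calibrated", t, state$crop)
        transition("IDLE")
        state$last_motivation <- t
      }
    }
    return(list(state = state, messages = out))
  }

  # sustained loss of the subject routes back to the full-body wait
  if (!full_body_visible(frame, cfg$vis_min)) {
    if (is.na(state$invis_since)) state$invis_since <- t
    if (t - state$invis_since >= 1) {
      transition("WAIT_FULL_BODY")
      state$vis_streak_start <- NA_real_
      state$activity_start <- NA_integer_
      state$invis_since <- NA_real_
      return(list(state = state, messages = out))
    }
  } else state$invis_since <- NA_real_

  if (t - state$last_eval < cfg$eval_interval || k < 8)
    return(list(state = state, messages = out))
  state$last_eval <- t

  if (state$mode == "IDLE") {
    from <- max(1L, k - as.integer(4 * state$fps))
    if (window_active(state, from)) {
      state$activity_start <- activity_onset(state, from)
      transition("RECOGNIZING")
    } else if (t - state$last_motivation >= cfg$idle_timeout) {
      emit("motivation", "Let's begin! Start your exercise")
      state$last_motivation <- t
    }
  } else if (state$mode == "RECOGNIZING") {
    from <- state$activity_start
    span <- state$t[k] - state$t[from]
    # activity fizzled before recognition: back to IDLE, nudge the user
    tail_from <- max(from, k - as.integer(2 * (cfg$pause_timeout + 1) * state$fps))
    if (trailing_pause_s(state, tail_from) >= cfg$pause_timeout) {
      transition("IDLE")
      state$last_motivation <- t - cfg$idle_timeout
      state$activity_start <- NA_integer_
      return(list(state = state, messages = out))
    }
    dom <- dominant_signal(state, from)
    per <- tryCatch(estimate_period(dom), error = function(e) NA_real_)
    # predict on the first completed repetition, aligned the same way the
    # training windows are; fall back to a fixed trailing window when no
    # period emerges
    win <- NULL
    if (!is.na(per)) {
      reps0 <- segment_repetitions(dom, per)
      if (nrow(reps0) >= 1)
        win <- c(from + reps0$start[1], from + min(reps0$end[1], k - from))
    }
    if (is.null(win)) {
      cyc <- first_cycle(dom)
      if (!is.null(cyc)) {
        per <- cyc$duration
        win <- c(from + cyc$start, from + min(cyc$end, k - from))
      } else if (span >= 2 * cfg$recog_fallback_s) {
        per <- cfg$recog_fallback_s
        win <- c(max(from, k - as.integer(per * state$fps)), k)
      }
    }
    if (!is.null(win) && win[2] - win[1] >= 8 && !is.null(state$model)) {
      state$period <- per
      basic <- select_basic_signals(
        extract_signals(window_seq(state, win[1], win[2])))
      pred <- predict_exercise(state$model, extract_features(basic))
      lab <- as.character(pred$label)
      state <- log_event(state, "prediction", t,
                         list(label = lab, score = pred$score))
      if (is.null(state$current_exercise) ||
          !identical(lab, state$current_exercise)) {
        state$current_exercise <- lab
        state$rep_count <- 0L
        emit("recognition", paste0("Exercise recognized: ", lab))
      }
      # re-estimate the period on the recognized exercise's driver signal,
      # but only once the window can hold two full cycles
      if (span >= 2 * per) {
        per2 <- tryCatch(
          estimate_period(dominant_signal(state, from, exercise = lab)),
          error = function(e) NA_real_)
        if (!is.na(per2)) state$period <- per2
      }
      state$base_count <- state$rep_count
      state$latched <- character(0)
      state$clean_streak <- 0L
      state$last_pred <- lab
      state$change_streak <- 0L
      transition("TRACKING")
    } else if (span > 4 * cfg$recog_fallback_s) {
      transition("IDLE")   # activity fizzled out before recognition
      state$activity_start <- NA_integer_
    }
  } else if (state$mode == "TRACKING") {
    from <- state$activity_start
    # inactivity check on the trailing window
    tail_from <- max(from, k - as.integer(2 * (cfg$pause_timeout + 1) * state$fps))
    if (trailing_pause_s(state, tail_from,
                         exercise = state$current_exercise) >= cfg$pause_timeout) {
      transition("IDLE")
      # inactivity after exercising draws an immediate motivation message
      state$last_motivation <- t - cfg$idle_timeout
      state$activity_start <- NA_integer_
      return(list(state = state, messages = out))
    }
    dom <- dominant_signal(state, from, exercise = state$current_exercise)
    # refresh the period estimate as the window grows
    if ((state$t[k] - state$t[from]) >= 2.5 * state$period) {
      per_new <- tryCatch(estimate_period(dom), error = function(e) NA_real_)
      if (!is.na(per_new)) state$period <- per_new
    }
    reps <- segment_repetitions(dom, state$period)
    completed <- state$base_count + nrow(reps)
    if (completed > state$rep_count) {
      new_reps <- (state$rep_count - state$base_count + 1L):nrow(reps)
      wseq <- window_seq(state, from)
      for (i in new_reps) {
        state$rep_count <- state$rep_count + 1L
        emit("count", paste0("Repetition ", state$rep_count))
        state <- log_event(state, "repetition", t,
                           list(count = state$rep_count))
        viol <- tryCatch(
          check_guidelines(state$current_exercise, wseq, reps[i, ],
                           tolerance = cfg$tolerance, period = state$period),
          error = function(e) no_violations())
        if (nrow(viol)) {
          state$clean_streak <- 0L
          state$latched <- unique(c(state$latched, viol$message))
        } else {
          state$clean_streak <- state$clean_streak + 1L
          if (state$clean_streak >= 1L) state$latched <- character(0)
        }
        for (m in state$latched) emit("correction", m)
        # exercise-change vote on this repetition's window
        if (!is.null(state$model)) {
          idx <- (reps$start[i] + 1L):min(reps$end[i], n_frames(wseq))
          if (length(idx) >= 8) {
            basic <- select_basic_signals(extract_signals(
              window_seq(state, from + idx[1] - 1L, from + idx[length(idx)] - 1L)))
            pred <- predict_exercise(state$model, extract_features(basic))
            lab <- as.character(pred$label)
            if (!identical(lab, state$current_exercise)) {
              state$change_streak <- state$change_streak + 1L
              if (state$change_streak >= cfg$change_votes) {
                state$current_exercise <- lab
                state$rep_count <- 0L
                state$base_count <- 0L
                state$activity_start <- from + reps$end[i]
                state$latched <- character(0)
                emit("recognition", paste0("Exercise recognized: ", lab))
                state <- log_event(state, "exercise_change", t,
                                   list(label = lab))
                break
              }
            } else state$change_streak <- 0L
          }
        }
      }
    } else if (length(state$latched)) {
      for (m in state$latched) emit("correction", m)
    }
  }
  list(state = state, messages = out)
}

# first active-sample index (global) of the trailing activity run
activity_onset <- function(state, from) {
  dom <- dominant_signal(state, from)
  seg <- detect_activity(dom)
  act <- seg[seg$kind == "active", , drop = FALSE]
  if (!nrow(act)) return(from)
  from + act$start[nrow(act)]
}

#' Run a complete session over a pose sequence
#'
#' Folds \code{\link{step}} over every frame and returns the ordered event
#' log.  Deterministic for a fixed sequence, model and configuration.
#'
#' @param source a \code{pose_sequence} (an offline recording or a
#'   simulated session).
#' @param model a \code{kinerehab_model} bundle.
#' @param config a \code{\link{session_config}}.
#' @return A \code{session_log}: data.frame with \code{t}, \code{type},
#'   \code{kind}, \code{text} plus the final \code{session_state} in
#'   attribute \code{"state"}.
#' @export
run_session <- function(source, model = NULL, config = session_config()) {
  stopifnot(inherits(source, "pose_sequence"))
  state <- new_session(model, config)
  for (i in seq_len(n_frames(source))) {
    res <- step(state, get_frame(source, i))
    state <- res$state
  }
  events <- state$log
  df <- data.frame(
    t = vapply(events, function(e) e$t, numeric(1)),
    type = vapply(events, function(e) e$type, character(1)),
    kind = vapply(events, function(e)
      if (e$type == "message") e$payload$kind else NA_character_, character(1)),
    text = vapply(events, function(e) {
      if (e$type == "message") e$payload$text
      else if (e$type == "transition") paste(e$payload$from, "->", e$payload$to)
      else if (e$type == "prediction") paste0("pred:", e$payload$label)
      else if (e$type == "repetition") paste0("rep:", e$payload$count)
      else if (e$type == "exercise_change") paste0("change:", e$payload$label)
      else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("session_log", "data.frame"), state = state)
}

#' Write a session log as JSON events
#'
#' @param log a \code{session_log}.
#' @param path output path.
#' @export
write_session_log <- function(log, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(log)), function(i)
      list(t = log$t[i], type = log$type[i],
           kind = log$kind[i], text = log$text[i])),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
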