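#' @title Pose sequences: the keypoint data model
#' @description
#' A \code{pose_sequence} stores a trial's worth of 33-landmark keypoint
#' frames as a dense numeric array \code{[frame, landmark, (x, y, z, v)]}
#' together with per-frame timestamps, the sampling rate and free-form
#' provenance metadata.  Coordinates follow the normalized image convention:
#' origin at the top-left, x to the right, y downwards, both nominally in
#' [0, 1]; z is a relative depth on the same scale (smaller = closer to the
#' camera) and v is a visibility score in [0, 1].
#' @name pose_sequence
NULL

FRAME_COLS <- c("x", "y", "z", "v")

#' Construct a pose sequence
#'
#' @param landmarks numeric array \code{n_frames x 33 x 4} (x, y, z,
#'   visibility), or a list of 33 x 4 frame matrices.
#' @param fps frames per second (> 0).
#' @param t optional per-frame timestamps in seconds; defaults to
#'   \code{(0:(n-1)) / fps}.
#' @param meta named list of provenance fields (source, subject id,
#'   exercise label if known).
#' @return An object of class \code{pose_sequence}.
#' @export
pose_sequence <- function(landmarks, fps, t = NULL, meta = list()) {
  if (is.list(landmarks)) {
    n <- length(landmarks)
    arr <- array(NA_real_, dim = c(n, N_LANDMARKS, 4L))
    for (i in seq_len(n)) {
      m <- landmarks[[i]]
      if (!is.matrix(m) || nrow(m) != N_LANDMARKS || ncol(m) != 4L)
        stop("frame ", i, " is not a 33 x 4 landmark matrix")
      arr[i, , ] <- m
    }
    landmarks <- arr
  }
  stopifnot(is.array(landmarks), length(dim(landmarks)) == 3L)
  if (dim(landmarks)[2] != N_LANDMARKS || dim(landmarks)[3] != 4L)
    stop("landmark array must be n x 33 x 4")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  n <- dim(landmarks)[1]
  if (is.null(t)) t <- (seq_len(n) - 1) / fps
  if (length(t) != n) stop("t must have one entry per frame")
  if (n > 1 && any(diff(t) < 0)) stop("timestamps must be nondecreasing")
  dimnames(landmarks) <- list(NULL, NULL, FRAME_COLS)
  structure(
    list(landmarks = landmarks, t = as.numeric(t), fps = fps, meta = meta),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf(
    "<pose_sequence> %d frames @ %.6g fps (%.2f s)\n",
    n_frames(x), x$fps, if (n_frames(x)) diff(range(x$t)) else 0
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq a \code{pose_sequence}.
#' @export
n_frames <- function(seq) dim(seq$landmarks)[1]

#' Extract one keypoint frame
#'
#' @param seq a \code{pose_sequence}.
#' @param i frame number (1-based).
#' @return A 33 x 4 matrix (columns x, y, z, v) of class
#'   \code{keypoint_frame}, with attributes \code{t} (seconds) and
#'   \code{index} (0-based frame ordinal).
#' @export
get_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  m <- seq$landmarks[i, , ]
  dimnames(m) <- list(NULL, FRAME_COLS)
  structure(m, t = seq$t[i], index = i - 1L, class = "keypoint_frame")
}

as_frame <- function(m) {
  if (!inherits(m, "keypoint_frame")) {
    stopifnot(is.matrix(m), nrow(m) == N_LANDMARKS, ncol(m) == 4L)
    colnames(m) <- FRAME_COLS
    class(m) <- "keypoint_frame"
  }
  m
}

# ---------------------------------------------------------------------------
# I/O: keypoint JSONL and CSV dialects
# ---------------------------------------------------------------------------

#' Write a pose sequence to disk
#'
#' Two plain-text dialects are supported.  JSONL: a header line
#' \code{{"fps": ..., "meta": {...}}} followed by one frame per line,
#' \code{{"index": i, "t": seconds, "landmarks": [[x,y,z,v] x 33]}}.
#' CSV: a comment header \code{# fps=...}, then columns \code{index, t,
#' k0_x, k0_y, k0_z, k0_v, ..., k32_v}.
#'
#' @param seq a \code{pose_sequence}.
#' @param path output file path.
#' @param dialect \code{"jsonl"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_keypoints <- function(seq, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  if (dialect == "jsonl") {
    header <- jsonlite::toJSON(list(fps = seq$fps, meta = seq$meta),
                               auto_unbox = TRUE, digits = NA)
    lines <- character(n + 1L)
    lines[1] <- header
    for (i in seq_len(n)) {
      lines[i + 1L] <- jsonlite::toJSON(
        list(index = i - 1L, t = seq$t[i],
             landmarks = unname(seq$landmarks[i, , , drop = TRUE])),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
      )
    }
    writeLines(lines, path)
  } else {
    cols <- as.vector(t(outer(0:(N_LANDMARKS - 1L), FRAME_COLS,
                              function(i, a) paste0("k", i, "_", a))))
    flat <- matrix(aperm(seq$landmarks, c(1L, 3L, 2L)), nrow = n)
    df <- data.frame(index = 0:(n - 1L), t = seq$t, flat)
    names(df) <- c("index", "t", cols)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fps=%.10g", seq$fps), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

#' Read a pose sequence from disk
#'
#' Counterpart of \code{\link{write_keypoints}}; validates the 33-landmark
#' invariant per frame and the presence of the fps metadata.
#'
#' @param path input file.
#' @param dialect \code{"jsonl"} or \code{"csv"}; guessed from the file
#'   extension when missing.
#' @return A validated \code{pose_sequence}.
#' @export
read_keypoints <- function(path, dialect = c("jsonl", "csv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(dialect) > 1L && !missing(dialect)) dialect <- dialect[1]
  if (missing(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  } else dialect <- match.arg(dialect)
  if (dialect == "jsonl") {
    lines <- readLines(path)
    if (!length(lines)) stop("empty keypoint file: ", path)
    header <- tryCatch(jsonlite::fromJSON(lines[1]),
                       error = function(e) stop("malformed header (line 1): ",
                                                conditionMessage(e)))
    if (is.null(header$fps)) stop("missing fps metadata in header")
    body <- lines[-1]
    n <- length(body)
    arr <- array(NA_real_, dim = c(n, N_LANDMARKS, 4L))
    t <- numeric(n)
    for (i in seq_len(n)) {
      rec <- tryCatch(jsonlite::fromJSON(body[i]),
                      error = function(e) stop("parse error at line ", i + 1L,
                                               ": ", conditionMessage(e)))
      lm <- rec$landmarks
      if (is.null(dim(lm)) || nrow(lm) != N_LANDMARKS || ncol(lm) != 4L)
        stop("parse error at line ", i + 1L, ": frame has ",
             if (is.null(dim(lm))) length(lm) else nrow(lm),
             " landmarks, expected 33")
      arr[i, , ] <- lm
      t[i] <- rec$t
    }
    meta <- header$meta
    if (is.null(meta)) meta <- list()
    pose_sequence(arr, fps = header$fps, t = t, meta = as.list(meta))
  } else {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("^#\\s*fps=([0-9.eE+-]+)", first))[[1]]
    if (length(m) < 2L) stop("missing fps metadata ('# fps=...' header line)")
    fps <- as.numeric(m[2])
    df <- utils::read.csv(path, comment.char = "#")
    need <- 2L + 4L * N_LANDMARKS
    if (ncol(df) != need)
      stop("parse error: expected ", need, " columns, found ", ncol(df))
    n <- nrow(df)
    arr <- array(NA_real_, dim = c(n, N_LANDMARKS, 4L))
    arr[] <- aperm(array(as.matrix(df[, -(1:2)]), dim = c(n, 4L, N_LANDMARKS)),
                   c(1L, 3L, 2L))
    pose_sequence(arr, fps = fps, t = df$t)
  }
}

# ---------------------------------------------------------------------------
# Body-centering geometry
# ---------------------------------------------------------------------------

#' Body center of a frame
#'
#' The midpoint between the two hip landmarks, the reference "center of the
#' body" used to place the personalized crop box.
#'
#' @param frame a \code{keypoint_frame} (33 x 4 matrix).
#' @param vis_min minimum hip visibility required (default 0.5).
#' @return Numeric \code{c(x, y)}.
#' @export
body_center <- function(frame, vis_min = 0.5) {
  frame <- as_frame(frame)
  lh <- frame[lm_row(BLAZEPOSE[["left_hip"]]), ]
  rh <- frame[lm_row(BLAZEPOSE[["right_hip"]]), ]
  if (lh["v"] < vis_min || rh["v"] < vis_min)
    stop("body not detected: hip visibility below ", vis_min)
  unname((lh[c("x", "y")] + rh[c("x", "y")]) / 2)
}

#' Reference distance (RDS): per-subject body scale
#'
#' Mean of the two arms' shoulder-to-index-finger Euclidean distances in the
#' image plane; sizes the crop box so that geometry is independent of the
#' subject's distance from the camera.
#'
#' @inheritParams body_center
#' @return Arm-length scale in normalized units.
#' @export
reference_distance <- function(frame, vis_min = 0.5) {
  frame <- as_frame(frame)
  idx <- lm_row(BLAZEPOSE[c("left_shoulder", "left_index",
                            "right_shoulder", "right_index")])
  if (any(frame[idx, "v"] < vis_min))
    stop("calibration failed: shoulder or index-finger landmark not visible")
  d <- function(a, b) sqrt(sum((frame[a, c("x", "y")] - frame[b, c("x", "y")])^2))
  (d(idx[1], idx[2]) + d(idx[3], idx[4])) / 2
}

#' Full-body visibility check
#'
#' TRUE iff every essential landmark (nose, shoulders, hips, knees, ankles)
#' is inside the image and scored at least \code{vis_min}.
#'
#' @inheritParams body_center
#' @param essential 0-based landmark ids to require (default
#'   \code{ESSENTIAL_LANDMARKS}).
#' @export
full_body_visible <- function(frame, vis_min = 0.5,
                              essential = ESSENTIAL_LANDMARKS) {
  frame <- as_frame(frame)
  rows <- lm_row(essential)
  all(frame[rows, "v"] >= vis_min) &&
    all(frame[rows, "x"] >= 0 & frame[rows, "x"] <= 1) &&
    all(frame[rows, "y"] >= 0 & frame[rows, "y"] <= 1)
}

#' Personalized crop box
#'
#' Center = median body center over the calibration window; half-extents =
#' \code{scale} times the median reference distance (a square box, clipped
#' to the unit image).  Computed once per session after full-body detection
#' rather than per frame, so camera jitter does not move the box.
#'
#' @param seq a \code{pose_sequence}.
#' @param calib_window seconds of leading frames to calibrate on (default 1).
#' @param scale box half-side as a multiple of the reference distance
#'   (default 2: box side = 4 arm lengths).
#' @param vis_min visibility threshold for calibration frames.
#' @return A list \code{crop_box(cx, cy, half_w, half_h)} with the clipped
#'   ranges in \code{$x_range}, \code{$y_range}.
#' @export
compute_crop_box <- function(seq, calib_window = 1, scale = 2, vis_min = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  in_win <- which(seq$t <= seq$t[1] + calib_window)
  ok <- Filter(function(i) full_body_visible(get_frame(seq, i), vis_min), in_win)
  if (!length(ok))
    stop("no valid calibration frame: step back until fully visible")
  centers <- vapply(ok, function(i) body_center(get_frame(seq, i), vis_min),
                    numeric(2))
  rds <- vapply(ok, function(i) reference_distance(get_frame(seq, i), vis_min),
                numeric(1))
  crop_box(cx = stats::median(centers[1, ]), cy = stats::median(centers[2, ]),
           half = scale * stats::median(rds))
}

#' @rdname compute_crop_box
#' @param cx,cy normalized box center.
#' @param half half-side of the (square) box before clipping.
#' @export
crop_box <- function(cx, cy, half) {
  stopifnot(half > 0)
  structure(list(
    cx = cx, cy = cy, half_w = half, half_h = half,
    x_range = c(max(0, cx - half), min(1, cx + half)),
    y_range = c(max(0, cy - half), min(1, cy + half))
  ), class = "crop_box")
}

# ---------------------------------------------------------------------------
# Keypoint-to-signal conversion
# ---------------------------------------------------------------------------

#' One keypoint-coordinate time series
#'
#' @param values numeric vector.
#' @param fs sampling rate in Hz (> 0).
#' @param label length-2 descriptor \code{c(keypoint, axis)} or any string.
#' @return An object of class \code{motion_signal}.
#' @export
motion_signal <- function(values, fs, label = c(NA, NA)) {
  stopifnot(is.numeric(values), fs > 0)
  if (any(!is.finite(values))) stop("motion signal values must be finite")
  structure(list(values = as.numeric(values), fs = fs, label = label),
            class = "motion_signal")
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf("<motion_signal %s> %d samples @ %g Hz\n",
              paste(x$label, collapse = "/"), length(x$values), x$fs))
  invisible(x)
}

#' Extract the 99 per-coordinate motion signals of a trial
#'
#' One \code{motion_signal} per (landmark, axis) pair: 33 keypoints times
#' the x, y and z coordinates = 99 time series, each as long as the trial.
#'
#' @param seq a non-empty \code{pose_sequence}.
#' @return A \code{signal_set}: list with \code{$signals} (named list of 99
#'   \code{motion_signal}, names \code{"k<i>_<axis>"}) and \code{$fs}.
#' @export
extract_signals <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"), n_frames(seq) >= 1)
  signals <- vector("list", N_LANDMARKS * 3L)
  nm <- character(N_LANDMARKS * 3L)
  k <- 0L
  for (i in 0:(N_LANDMARKS - 1L)) {
    for (axis in AXES) {
      k <- k + 1L
      signals[[k]] <- motion_signal(seq$landmarks[, lm_row(i), axis],
                                    fs = seq$fps, label = c(i, axis))
      nm[k] <- paste0("k", i, "_", axis)
    }
  }
  names(signals) <- nm
  structure(list(signals = signals, fs = seq$fps), class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d signals @ %g Hz, %d samples each\n",
              length(x$signals), x$fs, length(x$signals[[1]]$values)))
  invisible(x)
}
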