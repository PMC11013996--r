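#' BlazePose landmark topology
#'
#' Index constants (0-based, as published) for the 33-landmark full-body
#' topology: face (0-10), arms (11-22), hips/legs/feet (23-32).  All package
#' code addresses landmarks by these 0-based indices; internally a frame is a
#' 33 x 4 matrix whose row \code{i + 1} holds landmark \code{i}.
#'
#' @format A named integer vector of length 33.
#' @export
BLAZEPOSE <- c(
  nose = 0L,
  left_eye_inner = 1L, left_eye = 2L, left_eye_outer = 3L,
  right_eye_inner = 4L, right_eye = 5L, right_eye_outer = 6L,
  left_ear = 7L, right_ear = 8L,
  mouth_left = 9L, mouth_right = 10L,
  left_shoulder = 11L, right_shoulder = 12L,
  left_elbow = 13L, right_elbow = 14L,
  left_wrist = 15L, right_wrist = 16L,
  left_pinky = 17L, right_pinky = 18L,
  left_index = 19L, right_index = 20L,
  left_thumb = 21L, right_thumb = 22L,
  left_hip = 23L, right_hip = 24L,
  left_knee = 25L, right_knee = 26L,
  left_ankle = 27L, right_ankle = 28L,
  left_heel = 29L, right_heel = 30L,
  left_foot_index = 31L, right_foot_index = 32L
)

N_LANDMARKS <- 33L
AXES <- c("x", "y", "z")

#' Essential landmarks for the full-body visibility check
#'
#' Nose, shoulders, hips, knees and ankles: the minimal set a frontal
#' tele-exercise camera must see before calibration can start.
#' @keywords internal
ESSENTIAL_LANDMARKS <- unname(BLAZEPOSE[c(
  "nose", "left_shoulder", "right_shoulder", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)])

#' Exercise repertoire labels
#'
#' The five-exercise repertoire: side steps (SS), shoulder abductions (SA),
#' trunk rotation (TR), standing forward bends (FB) and squats (SQT),
#' numbered 1-5 in that order for classification.
#' @export
EXERCISES <- c(SS = 1L, SA = 2L, TR = 3L, FB = 4L, SQT = 5L)

# row index into the 33 x 4 landmark matrix for 0-based landmark id
lm_row <- function(id) id + 1L
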