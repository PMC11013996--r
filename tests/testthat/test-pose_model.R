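test_that("keypoint files round-trip through both dialects", {
  sim <- sim_trial("SA", 150, 2.5, n_reps = 2, noise_sd = 0.002, seed = 3)
  seq <- sim$seq
  for (dialect in c("jsonl", "csv")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_keypoints(seq, path, dialect)
    back <- read_keypoints(path, dialect)
    expect_equal(n_frames(back), n_frames(seq))
    expect_equal(back$fps, seq$fps)
    expect_equal(back$landmarks, seq$landmarks, tolerance = 1e-9)
    expect_equal(back$t, seq$t, tolerance = 1e-9)
    unlink(path)
  }
})

test_that("malformed keypoint files are rejected with informative errors", {
  # a frame with 32 landmarks
  path <- tempfile(fileext = ".jsonl")
  lm32 <- lapply(1:32, function(i) c(0.5, 0.5, 0, 1))
  writeLines(c(
    jsonlite::toJSON(list(fps = 30, meta = list()), auto_unbox = TRUE),
    jsonlite::toJSON(list(index = 0, t = 0, landmarks = lm32),
                     auto_unbox = TRUE)
  ), path)
  expect_error(read_keypoints(path, "jsonl"), "32 landmarks")
  # missing fps header
  writeLines(jsonlite::toJSON(list(meta = list()), auto_unbox = TRUE), path)
  expect_error(read_keypoints(path, "jsonl"), "fps")
  unlink(path)
  expect_error(read_keypoints(tempfile(), "jsonl"), "no such file")
})

test_that("a 150-frame trace at 30 fps spans five seconds", {
  sim <- sim_trial("SS", 40, 2.5, n_reps = 2, noise_sd = 0, seed = 1)
  expect_equal(n_frames(sim$seq), 150)
  expect_equal(diff(range(sim$seq$t)), 149 / 30, tolerance = 1e-9)
})

test_that("body center is the hip midpoint and respects visibility", {
  f <- standing_frame()
  f[lm_row(BLAZEPOSE[["left_hip"]]), ] <- c(0.4, 0.6, 0, 1)
  f[lm_row(BLAZEPOSE[["right_hip"]]), ] <- c(0.6, 0.6, 0, 1)
  expect_equal(body_center(f), c(0.5, 0.6))
  f[lm_row(BLAZEPOSE[["left_hip"]]), ] <- c(0.5, 0.5, 0, 1)
  f[lm_row(BLAZEPOSE[["right_hip"]]), ] <- c(0.5, 0.5, 0, 1)
  expect_equal(body_center(f), c(0.5, 0.5))
  f[lm_row(BLAZEPOSE[["left_hip"]]), "v"] <- 0.2
  expect_error(body_center(f), "not detected")
  # generator ground truth: pelvis at the configured neutral position
  g <- standing_frame()
  expect_equal(body_center(g), c(0.5, 0.6), tolerance = 1e-9)
})

test_that("reference distance averages both arm lengths", {
  f <- standing_frame()
  f[lm_row(BLAZEPOSE[["left_shoulder"]]), 1:2] <- c(0.6, 0.4)
  f[lm_row(BLAZEPOSE[["left_index"]]), 1:2] <- c(0.6, 0.7)   # length 0.30
  f[lm_row(BLAZEPOSE[["right_shoulder"]]), 1:2] <- c(0.4, 0.4)
  f[lm_row(BLAZEPOSE[["right_index"]]), 1:2] <- c(0.4, 0.8)  # length 0.40
  expect_equal(reference_distance(f), 0.35)
  # symmetric standing skeleton: arm length equals the configured 0.25
  expect_equal(reference_distance(standing_frame()), 0.25, tolerance = 1e-9)
  f[lm_row(BLAZEPOSE[["left_index"]]), "v"] <- 0
  expect_error(reference_distance(f), "calibration failed")
})

test_that("reference distance is rotation invariant", {
  f <- standing_frame()
  base <- reference_distance(f)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g <- f
  g[, 1:2] <- sweep(f[, 1:2], 2, c(0.5, 0.5)) %*% R +
    matrix(rep(c(0.5, 0.5), each = 33), ncol = 2)
  expect_equal(reference_distance(as_frame <- structure(g, class = "keypoint_frame")),
               base, tolerance = 1e-12)
})

test_that("full-body visibility check catches cropping and low scores", {
  f <- standing_frame()
  expect_true(full_body_visible(f))
  g <- f; g[lm_row(BLAZEPOSE[["left_ankle"]]), "y"] <- 1.05
  expect_false(full_body_visible(g))
  h <- f; h[lm_row(BLAZEPOSE[["nose"]]), "v"] <- 0.1
  expect_false(full_body_visible(h))
  # generator error injection: lower body cropped out of frame
  sim <- simulate_motion(motion_script(list(
    motion_phase("SA", 150, 2.5, n_reps = 1, errors = "partial_body")
  ), noise_sd = 0, seed = 1))
  expect_false(full_body_visible(get_frame(sim$seq, 1)))
})

test_that("crop box arithmetic, clipping and containment hold", {
  b <- crop_box(0.5, 0.5, 0.4)
  expect_equal(b$x_range, c(0.1, 0.9))
  expect_equal(b$y_range, c(0.1, 0.9))
  b2 <- crop_box(0.9, 0.5, 0.4)
  expect_equal(b2$x_range, c(0.5, 1.0))
  # stationary subject: computed box contains every landmark of every frame
  sim <- sim_trial("SS", 30, 2, n_reps = 3, noise_sd = 0.002, seed = 2)
  box <- compute_crop_box(sim$seq, calib_window = 1, scale = 2)
  xs <- sim$seq$landmarks[, , "x"]; ys <- sim$seq$landmarks[, , "y"]
  expect_true(all(xs >= box$x_range[1] - 0.02 & xs <= box$x_range[2] + 0.02))
  expect_true(all(ys >= box$y_range[1] - 0.02 & ys <= box$y_range[2] + 0.02))
})

test_that("crop box translates with the subject", {
  sim <- sim_trial("SS", 30, 2, n_reps = 2, noise_sd = 0, seed = 2)
  b1 <- compute_crop_box(sim$seq)
  shifted <- sim$seq
  shifted$landmarks[, , "x"] <- shifted$landmarks[, , "x"] - 0.1
  b2 <- compute_crop_box(shifted)
  expect_equal(b2$cx, b1$cx - 0.1, tolerance = 1e-9)
  expect_equal(b2$cy, b1$cy, tolerance = 1e-9)
  expect_equal(b2$half_w, b1$half_w, tolerance = 1e-9)
})

test_that("signal extraction yields 99 aligned series", {
  sim <- sim_trial("TR", 45, 3, n_reps = 2, noise_sd = 0.002, seed = 4)
  ss <- extract_signals(sim$seq)
  expect_length(ss$signals, 99)
  expect_true(all(vapply(ss$signals, function(s) length(s$values),
                         integer(1)) == n_frames(sim$seq)))
  expect_equal(ss$fs, sim$seq$fps)
  # the (23, x) signal is the left-hip x trace
  expect_equal(ss$signals[["k23_x"]]$values,
               sim$seq$landmarks[, lm_row(23L), "x"])
  # one-frame edge case
  one <- pose_sequence(sim$seq$landmarks[1, , , drop = FALSE], fps = 30)
  ss1 <- extract_signals(one)
  expect_length(ss1$signals, 99)
  expect_true(all(vapply(ss1$signals, function(s) length(s$values),
                         integer(1)) == 1L))
})
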