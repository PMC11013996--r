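test_that("joint angle matches closed forms and the atan2 oracle", {
  expect_equal(joint_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(joint_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 0)), "degenerate")
  set.seed(13)
  for (i in 1:10000) {
    a <- runif(2); b <- runif(2); c <- runif(2)
    if (sqrt(sum((a - b)^2)) < 1e-6 || sqrt(sum((c - b)^2)) < 1e-6) next
    got <- joint_angle(a, b, c)
    expect_lt(abs(got - atan2_angle(a, b, c)), 1e-9)
    expect_gte(got, 0); expect_lte(got, 180)
  }
})

test_that("joint angle is invariant under rigid motion and scaling", {
  set.seed(17)
  for (i in 1:200) {
    a <- runif(2); b <- runif(2); c <- runif(2)
    if (sqrt(sum((a - b)^2)) < 1e-4 || sqrt(sum((c - b)^2)) < 1e-4) next
    base <- joint_angle(a, b, c)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.2, 5); d <- runif(2, -3, 3)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- function(p) as.numeric(s * R %*% p + d)
    expect_lt(abs(joint_angle(tr(a), tr(b), tr(c)) - base), 1e-8)
  }
})

test_that("angle series recover generator joint angles", {
  # SA with elbows straight: elbow angle stays at 180 within 2 degrees
  sim <- sim_trial("SA", 150, 2.5, n_reps = 3, noise_sd = 0.0003, seed = 2)
  el <- angle_series(sim$seq, joint_triplet(11, 13, 15))
  expect_true(all(abs(el$values - 180) < 2))
  # static pose gives a constant series
  idle <- simulate_motion(motion_script(list(
    motion_phase("idle", duration_s = 2)), noise_sd = 0, seed = 1))
  kn <- angle_series(idle$seq, joint_triplet(23, 25, 27))
  expect_lt(diff(range(kn$values)), 1e-9)
  # SS with 45-degree abduction: hip series peak-to-peak close to 45
  sim2 <- sim_trial("SS", 45, 2, n_reps = 4, noise_sd = 0.001, seed = 3)
  hip <- angle_series(sim2$seq, joint_triplet(11, 23, 27))
  expect_lt(abs(diff(range(hip$values)) - 45), 2)
})

test_that("angle series interpolate sparse dropouts but reject heavy loss", {
  sim <- sim_trial("SA", 150, 2.5, n_reps = 2, noise_sd = 0, seed = 2)
  seq <- sim$seq
  drop <- seq(10, 20, by = 5)
  seq$landmarks[drop, lm_row(13L), "v"] <- 0.1
  el <- angle_series(seq, joint_triplet(11, 13, 15))
  expect_true(all(is.finite(el$values)))
  seq$landmarks[1:40, lm_row(13L), "v"] <- 0.1
  expect_error(angle_series(seq, joint_triplet(11, 13, 15)), "unreliable")
})

test_that("clean generator output reproduces the driven angle profile", {
  sim <- sim_trial("SA", 120, 3, n_reps = 2, noise_sd = 0, seed = 1)
  ang <- angle_series(sim$seq, joint_triplet(23, 11, 15))$values
  t <- (seq_along(ang) - 1) / 30
  driven <- 120 * (1 - cos(2 * pi * t / 3)) / 2
  expect_lt(max(abs((ang - ang[1]) - driven)), 0.5)
})

test_that("ROM summary takes the median of per-repetition maxima", {
  fake_reps <- data.frame(start = (0:4) * 10, end = (1:5) * 10,
                          duration = rep(10 / 30, 5))
  x <- numeric(50)
  for (i in 1:5) x[(i - 1) * 10 + 1:10] <- c(0, 0, 2, 5, c(40, 42, 44, 43, 41)[i], 5, 2, 0, 0, 0)
  rs <- rom_summary(motion_signal(x, 30), fake_reps, mode = "absolute", q = 0)
  expect_equal(rs$per_rep_max, c(40, 42, 44, 43, 41))
  expect_equal(rs$median_max, 42)
  one <- rom_summary(motion_signal(c(0, 25, 50, 25, 0), 30),
                     data.frame(start = 0, end = 5, duration = 1/6),
                     mode = "absolute", q = 0)
  expect_equal(one$median_max, 50)
  expect_error(rom_summary(motion_signal(x, 30), fake_reps[0, ]), "empty")
})

test_that("ROM is recovered within 2 degrees across the parameter grid", {
  for (rom in c(20, 40, 60, 90)) for (P in c(2, 3)) {
    sim <- sim_trial("SA", rom, P, n_reps = 5, noise_sd = 0.003,
                     seed = rom + P)
    a <- analyze_trial(sim$seq, "SA")
    expect_lt(abs(a$rom$shoulder_abduction_left$rom$median_max - rom), 2)
    expect_lt(abs(a$rom$shoulder_abduction_right$rom$median_max - rom), 2)
  }
})

test_that("angular velocity follows its definition", {
  expect_equal(angular_velocity(1.0, 2.0), 0.5)
  expect_equal(angular_velocity(pi, 1), pi)
  expect_error(angular_velocity(1, 0), "positive")
  # squat with ~1.2 rad hip excursion over 2.4 s repetitions
  sim <- sim_trial("SQT", rad2deg(1.2), 2.4, n_reps = 5, noise_sd = 0.002,
                   seed = 4)
  a <- analyze_trial(sim$seq, "SQT")
  expect_lt(abs(a$rom$squat_hip_flexion_left$omega_rad_s - 0.5), 0.05)
})

test_that("trunk rotation derives from shoulder-width foreshortening", {
  f <- standing_frame()
  w <- abs(f[lm_row(BLAZEPOSE[["left_shoulder"]]), "x"] -
             f[lm_row(BLAZEPOSE[["right_shoulder"]]), "x"])
  expect_equal(abs(trunk_rotation_angle(f, w)), 0, tolerance = 1e-6)
  expect_equal(abs(trunk_rotation_angle(f, 2 * w)), 60, tolerance = 1e-6)
  expect_error(trunk_rotation_angle(f, 0), "calibration")
  # parameter recovery on a 45-degree rotation trial
  sim <- sim_trial("TR", 45, 3, n_reps = 4, noise_sd = 0.002, seed = 5)
  a <- analyze_trial(sim$seq, "TR")
  expect_lt(abs(a$rom$lumbar_rotation$rom$median_max - 45), 3)
})

test_that("coordination recovers constructed lags", {
  t <- (0:599) / 30
  a <- sin(2 * pi * t / 2); b <- sin(2 * pi * (t - 0.3) / 2)
  co <- coordination(list(A = motion_signal(a, 30), B = motion_signal(b, 30)),
                     unify_threshold = 0.15)
  expect_equal(co$lag_matrix["A", "B"], 0.3, tolerance = 1 / 30)
  expect_equal(co$order, c("A", "B"))
  expect_false(co$unified)
  ident <- coordination(list(A = motion_signal(a, 30),
                             B = motion_signal(a, 30)),
                        unify_threshold = 0.15)
  expect_equal(ident$lag_matrix["A", "B"], 0)
  expect_true(ident$unified)
  expect_error(coordination(list(A = motion_signal(a, 30),
                                 B = motion_signal(rep(1, 600), 30))),
               "phase")
})

test_that("coordination lag matrix is antisymmetric with zero diagonal", {
  set.seed(23)
  t <- (0:449) / 30
  sigs <- lapply(c(0, 0.2, 0.45), function(d)
    motion_signal(sin(2 * pi * (t - d) / 3) + rnorm(450, 0, 0.05), 30))
  names(sigs) <- c("p1", "p2", "p3")
  co <- coordination(sigs, unify_threshold = 0.1)
  expect_equal(co$lag_matrix, -t(co$lag_matrix))
  expect_true(all(diag(co$lag_matrix) == 0))
  expect_equal(co$order, c("p1", "p2", "p3"))
  # recovered lags exact to one sample
  expect_lt(abs(co$lag_matrix["p1", "p2"] - 0.2), 1 / 30 + 1e-9)
  expect_lt(abs(co$lag_matrix["p1", "p3"] - 0.45), 1 / 30 + 1e-9)
})

test_that("arms trail the trunk in clean trunk rotation", {
  sim <- sim_trial("TR", 45, 3, n_reps = 4, noise_sd = 0.001, seed = 6)
  co <- kinerehab:::tr_unified_check(sim$seq, period = 3)
  expect_equal(co$order[1], "trunk")
  expect_false(co$unified)
})

test_that("guideline checks stay silent on clean execution", {
  for (ex in c("SS", "SA", "TR", "FB", "SQT")) for (seed in 1:3) {
    tpl <- kinerehab:::EXERCISE_TEMPLATES[[ex]]
    sim <- sim_trial(ex, tpl$rom_deg, tpl$period_s, n_reps = 4,
                     noise_sd = 0.003, seed = seed * 11)
    a <- analyze_trial(sim$seq, ex)
    expect_equal(nrow(a$violations), 0,
                 info = paste("clean", ex, "seed", seed))
  }
})

test_that("injected execution errors are flagged on every repetition", {
  cases <- list(
    c("SA", "bent_elbow", "Keep the arms straight!"),
    c("FB", "bent_knee", "Keep the legs straight"),
    c("SQT", "knees_past_toes", "Keep knees behind toes"),
    c("TR", "unified_trunk_rotation",
      "Rotate the trunk, not the whole body as one unit")
  )
  for (cs in cases) {
    tpl <- kinerehab:::EXERCISE_TEMPLATES[[cs[1]]]
    sim <- sim_trial(cs[1], tpl$rom_deg, tpl$period_s, n_reps = 4,
                     noise_sd = 0.002, seed = 7, errors = cs[2])
    a <- analyze_trial(sim$seq, cs[1])
    expect_true(cs[3] %in% a$violations$message, info = cs[1])
    if (cs[1] %in% c("SA", "FB"))
      expect_equal(sort(unique(a$violations$repetition)), 1:4, info = cs[1])
    expect_true(all(a$violations$severity >= 0.15 - 1e-9 |
                      is.na(a$violations$repetition)))
  }
})

test_that("the elbow guideline threshold follows the tolerance band", {
  # elbow driven to 140 degrees of extension deficit crosses the
  # 180 * (1 - 0.15) = 153 degree threshold
  sim <- sim_trial("SA", 150, 2.5, n_reps = 3, noise_sd = 0.002, seed = 8,
                   errors = "bent_elbow", bent_elbow_deg = 40)
  el <- angle_series(sim$seq, joint_triplet(11, 13, 15))$values
  expect_lt(min(el), 153)
  a <- analyze_trial(sim$seq, "SA")
  sa <- a$violations[a$violations$rule == "extended_arms", ]
  expect_equal(sort(unique(sa$repetition)), 1:3)
  expect_error(check_guidelines("SA", sim$seq, a$reps, tolerance = 0.5),
               "tolerance")
  expect_error(check_guidelines("XX", sim$seq, a$reps), "unknown")
})

test_that("normative comparison reports ratios and flags deficits", {
  expect_equal(compare_to_normative(40, "hip_abduction")$ratio, 1.0)
  sh <- compare_to_normative(90, "shoulder_abduction")
  expect_equal(sh$ratio, 0.5)
  expect_true(sh$below_norm)
  expect_equal(compare_to_normative(85, "squat_knee_flexion")$ratio, 1.0)
  expect_error(compare_to_normative(40, "elbow_extension"), "unknown")
})
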