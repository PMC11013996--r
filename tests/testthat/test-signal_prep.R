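test_that("amplitude modulation matches its definition", {
  expect_equal(amplitude_modulation(motion_signal(c(0.5, 0.5, 0.5), 30)),
               c(0, 0))
  expect_equal(amplitude_modulation(motion_signal(c(0.5, 1.0), 30)), 100)
  # brute-force oracle over a sinusoid
  x <- 0.5 + 0.1 * sin(2 * pi * (0:99) / 30)
  m <- amplitude_modulation(motion_signal(x, 30), eps = 1e-3)
  brute <- sapply(1:99, function(i)
    100 * abs(x[i + 1] - x[i]) / max(abs(x[i]), 1e-3))
  expect_equal(m, brute, tolerance = 1e-12)
  expect_error(amplitude_modulation(motion_signal(0.5, 30)), "2 samples")
})

test_that("activity detection partitions the trace and finds motion", {
  seg <- detect_activity(motion_signal(rep(0.5, 120), 30))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$kind, "pause")
  expect_equal(c(seg$start, seg$end), c(0, 120))

  # flat | 3 s large sinusoid | flat
  x <- c(rep(0.5, 90), 0.5 + 0.1 * sin(2 * pi * (0:89) / 30), rep(0.5, 90))
  set.seed(5)
  seg <- detect_activity(motion_signal(x + rnorm(270, 0, 0.002), 30))
  expect_equal(seg$kind, c("pause", "active", "pause"))
  expect_lt(abs(seg$start[2] - 90) / 30, 0.5)
  expect_lt(abs(seg$end[2] - 180) / 30, 0.5)

  # exercise with no pauses: one active segment covering everything
  sim <- sim_trial("SA", 150, 2.5, n_reps = 4, noise_sd = 0.002, seed = 6)
  dom <- segmentation_signal(sim$seq)
  seg <- detect_activity(dom)
  act <- seg[seg$kind == "active", ]
  expect_equal(nrow(act), 1)
  expect_lt(act$start / 30, 0.7)
  expect_gt(act$end / 30, n_frames(sim$seq) / 30 - 0.7)
})

test_that("activity segments are a disjoint ordered cover", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(60:400, 1)
    x <- cumsum(rnorm(n, 0, 0.01)) + 0.5
    seg <- detect_activity(motion_signal(x, 30))
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], n)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
      expect_true(all(diff(seg$start) > 0))
    }
    expect_true(all(seg$end > seg$start))
  }
})

test_that("moving average equals the brute-force window mean", {
  expect_equal(moving_average(motion_signal(c(1, 2, 3), 30), 0)$values,
               c(1, 2, 3))
  expect_equal(moving_average(motion_signal(c(0, 3, 0), 30), 1)$values[2], 1)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    M <- sample(0:6, 1)
    x <- rnorm(n)
    got <- moving_average(motion_signal(x, 30), M)$values
    want <- sapply(seq_len(n), function(j)
      mean(x[max(1, j - M):min(n, j + M)]))
    expect_identical(round(got, 12), round(want, 12))
  }
})

test_that("SSA components are summable and separate trend from periodicity", {
  fs <- 30; t <- (0:299) / fs
  ramp <- 0.3 * t / 10
  sine <- 0.1 * sin(2 * pi * 0.5 * t)
  set.seed(2)
  x <- ramp + sine + rnorm(300, 0, 0.001)
  d <- ssa_decompose(motion_signal(x, fs))
  expect_equal(nrow(d$components), 12)
  expect_lt(max(abs(colSums(d$components) - x)) / diff(range(x)), 1e-8)
  expect_lt(max(abs(d$trend + d$periodic + d$noise - x)) / diff(range(x)),
            1e-8)
  # pure ramp: trend tracks it
  d2 <- ssa_decompose(motion_signal(ramp + 0.2, fs))
  expect_gt(cor(d2$trend, ramp), 0.999)
  # ramp + sinusoid: trend approximates ramp, periodic captures the sinusoid
  expect_lt(sqrt(mean((d$trend - ramp)^2)) / diff(range(ramp)), 0.05)
  expect_gt(1 - sum((d$periodic - sine)^2) / sum(sine^2), 0.90)
  expect_error(ssa_decompose(motion_signal(rnorm(10), 30), L = 20), "exceed")
})

test_that("detrending subtracts exactly the SSA trend", {
  fs <- 30; t <- (0:299) / fs
  sine <- 0.1 * sin(2 * pi * 0.5 * t)
  d <- ssa_decompose(motion_signal(sine, fs))
  out <- detrend(motion_signal(sine, fs), d)
  expect_equal(sine - out$values, d$trend, tolerance = 1e-12)
  expect_lt(sqrt(mean((out$values - sine)^2)) / 0.1, 0.02)
  ramp <- 0.3 * t / 10
  d2 <- ssa_decompose(motion_signal(ramp, fs))
  out2 <- detrend(motion_signal(ramp, fs), d2)
  expect_lt(sqrt(mean(out2$values^2)) / diff(range(ramp)), 0.05)
})

test_that("period estimation recovers constructed periods", {
  t <- (0:299) / 30
  p <- estimate_period(motion_signal(sin(2 * pi * t / 2), 30))
  expect_lt(abs(p - 2), 1 / 30)
  set.seed(9)
  expect_error(estimate_period(motion_signal(rnorm(300), 30)), "aperiodic")
  sim <- sim_trial("SA", 150, 3, n_reps = 4, noise_sd = 0.003, seed = 8)
  p2 <- estimate_period(segmentation_signal(sim$seq))
  expect_lt(abs(p2 - 3), 1 / 15)
})

test_that("period recovery succeeds across periods and noise levels", {
  fails <- 0; trials <- 0
  for (P in c(1, 2, 3, 4)) for (ns in c(0, 0.01, 0.02)) for (seed in 1:9) {
    set.seed(seed * 1000 + P * 10 + round(ns * 100))
    x <- sin(2 * pi * (0:599) / 30 / P) + rnorm(600, 0, ns * 20)
    p <- tryCatch(estimate_period(motion_signal(x, 30)),
                  error = function(e) NA_real_)
    trials <- trials + 1
    if (is.na(p) || abs(p - P) > 1.5 / 30) fails <- fails + 1
  }
  expect_gte((trials - fails) / trials, 0.95)
})

test_that("repetition segmentation counts clean repetitions exactly", {
  for (k in 1:10) {
    sim <- sim_trial("SA", 150, 2.5, n_reps = k, noise_sd = 0.002, seed = k)
    dom <- segmentation_signal(sim$seq)
    per <- if (k >= 2) estimate_period(dom) else 2.5
    reps <- segment_repetitions(dom, per)
    expect_equal(nrow(reps), k)
    expect_true(all(reps$duration >= 0.5 * per & reps$duration <= 1.5 * per))
    expect_true(all(reps$end[-nrow(reps)] <= reps$start[-1] + 1e-9))
  }
})

test_that("a trailing half repetition is not counted", {
  # 1.5 periods of a raised-cosine profile
  t <- (0:89) / 30
  x <- 0.5 + 0.1 * (1 - cos(2 * pi * t / 2)) / 2
  reps <- segment_repetitions(motion_signal(x, 30), 2)
  expect_equal(nrow(reps), 1)
  # empty active region
  expect_equal(nrow(segment_repetitions(motion_signal(rep(0.5, 30), 30), 2)), 0)
  # period longer than the signal
  expect_equal(nrow(segment_repetitions(motion_signal(x, 30), 10)), 0)
})

test_that("first_cycle fires after a single completed repetition", {
  t <- (0:74) / 30     # 2.5 s: one 2 s cycle plus a bit
  x <- 0.5 + 0.1 * (1 - cos(2 * pi * pmin(t, 2) / 2)) / 2
  cyc <- first_cycle(motion_signal(x, 30))
  expect_false(is.null(cyc))
  expect_lt(abs(cyc$duration - 2), 0.3)
  expect_null(first_cycle(motion_signal(rep(0.5, 75), 30)))
})
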