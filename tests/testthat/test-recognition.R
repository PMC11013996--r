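test_that("basic-signal selection returns 15 deterministic series", {
  sim <- sim_trial("SA", 150, 2.5, n_reps = 2, noise_sd = 0.002, seed = 1)
  ss <- extract_signals(sim$seq)
  b1 <- select_basic_signals(ss)
  b2 <- select_basic_signals(ss)
  expect_length(b1, 15)
  expect_identical(names(b1), names(b2))
  expect_identical(lapply(b1, `[[`, "values"), lapply(b2, `[[`, "values"))
  # wrists and ankles match the raw trajectories
  expect_equal(b1[["left_arm_x"]]$values,
               sim$seq$landmarks[, lm_row(15L), "x"])
  expect_equal(b1[["right_leg_y"]]$values,
               sim$seq$landmarks[, lm_row(28L), "y"])
  # torso is the virtual mid-hip point
  expect_equal(b1[["torso_x"]]$values,
               (sim$seq$landmarks[, lm_row(23L), "x"] +
                  sim$seq$landmarks[, lm_row(24L), "x"]) / 2)
})

test_that("feature extraction produces a named 285-vector", {
  sim <- sim_trial("TR", 45, 3, n_reps = 2, noise_sd = 0.002, seed = 2)
  basic <- select_basic_signals(extract_signals(sim$seq))
  fv <- extract_features(basic)
  expect_length(fv, 285)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))
  short <- lapply(basic, function(s) motion_signal(s$values[1:4], s$fs))
  expect_error(extract_features(short), "too short")
})

test_that("feature closed forms hold for constant and sinusoidal input", {
  blk <- kinerehab:::feature_block(rep(0.5, 64), 30)
  expect_equal(unname(blk[c("mean", "max", "min", "rms", "median")]),
               rep(0.5, 5))
  expect_equal(unname(blk[c("variance", "p2p", "kurtosis", "skewness")]),
               rep(0, 4))
  expect_equal(unname(blk["crest"]), 1)
  expect_equal(unname(blk["energy"]), 64 * 0.25)
  # unit sinusoid with integer cycles
  n <- 300; f0 <- 2; fs <- 30
  x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  blk2 <- kinerehab:::feature_block(x, fs)
  expect_equal(unname(blk2["rms"]), 1 / sqrt(2), tolerance = 1e-3)
  expect_lt(abs(blk2[["bp_peakf"]] - f0), fs / n + 1e-9)
})

test_that("every time-domain feature matches its direct formula", {
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(16:128, 1), sd = runif(1, 0.1, 3))
    blk <- kinerehab:::feature_block(x, 30)
    want <- oracle_time_features(x)
    expect_lt(max(abs(blk[names(want)] - want)), 1e-10)
  }
})

test_that("PCA retains the right subspace and satisfies its identities", {
  set.seed(37)
  n <- 120
  basis <- qr.Q(qr(matrix(rnorm(285 * 3), ncol = 3)))
  X <- matrix(rnorm(n * 3), ncol = 3) %*% t(basis) * 10 +
    matrix(rnorm(n * 285, 0, 1e-4), ncol = 285)
  colnames(X) <- paste0("f", 1:285)
  pm <- fit_pca(X, target_var = 0.90)
  expect_equal(pm$n_retained, 3)
  expect_equal(crossprod(pm$rotation), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pm$var_frac) <= 1e-12))
  expect_lte(sum(pm$var_frac), 1 + 1e-9)
  # retained space reconstructs at least the target variance
  Z <- sweep(sweep(X, 2, pm$center), 2, pm$scale, "/")
  Zr <- transform_pca(pm, X) %*% t(pm$rotation)
  expect_gte(1 - sum((Z - Zr)^2) / sum(sweep(Z, 2, colMeans(Z))^2), 0.90)
  expect_error(fit_pca(matrix(1, 10, 285)), "degenerate")
})

test_that("PCA on isotropic noise needs most of the spectrum", {
  # with no low-rank structure the sample spectrum is Marchenko-Pastur
  # spread, so 90% of the variance still demands the bulk of the available
  # components -- in sharp contrast to the rank-3 case above
  set.seed(41)
  X <- matrix(rnorm(80 * 285), ncol = 285)
  pm <- fit_pca(X, target_var = 0.90)
  expect_gte(pm$n_retained, 0.7 * 79)
  expect_lte(pm$n_retained, 79)
})

test_that("subject-wise splits hit the target fraction without leakage", {
  subjects <- rep(1:10, each = 10)
  sp <- split_by_subject(subjects, 0.30, seed = 3)
  expect_length(sp$test_subjects, 3)
  expect_length(sp$test_idx, 30)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  sp2 <- split_by_subject(subjects, 0.30, seed = 3)
  expect_identical(sp$test_subjects, sp2$test_subjects)
  expect_error(split_by_subject(rep(1, 10)), "2 subjects")
  # imbalanced subjects still land near the target
  imb <- rep(1:6, times = c(40, 5, 5, 5, 5, 40))
  spi <- split_by_subject(imb, 0.30, seed = 5)
  expect_lt(abs(spi$achieved_fraction - 0.30), 0.45)
})

test_that("the classifier battery separates the synthetic repertoire", {
  rep <- fixture_report()
  m <- rep$metrics
  expect_setequal(m$classifier, c("RF", "SVML", "SVMP", "SVMRBF", "DT"))
  expect_gte(m$accuracy[m$classifier == "SVML"], 99)
  expect_lte(m$accuracy[m$classifier == "DT"],
             m$accuracy[m$classifier == "RF"] + 1e-9)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 100))
  expect_true(all(rowSums(rep$confusion$SVML) > 0))
})

test_that("evaluation guards against leakage and missing classes", {
  feat <- fixture_features()
  bad <- fixture_split()
  bad$test_idx <- bad$test_idx[-1]        # a test subject's row leaks to train
  expect_error(train_and_evaluate(feat$X, feat$y, feat$subjects, bad,
                                  use_pca = FALSE, cv_folds = 0, seed = 1),
               "leakage")
  drop <- feat$y != "TR" | seq_along(feat$y) %in% fixture_split()$test_idx
  expect_error(train_and_evaluate(feat$X[drop, ], feat$y[drop],
                                  feat$subjects[drop],
                                  local({
                                    s <- fixture_split()
                                    s$test_idx <- which(seq_along(feat$y)[drop] %in% s$test_idx)
                                    s
                                  }),
                                  use_pca = FALSE, cv_folds = 0, seed = 1),
               "missing")
})

test_that("prediction returns its own label on training data", {
  feat <- fixture_features()
  model <- fixture_model()
  tr_idx <- setdiff(seq_len(nrow(feat$X)), fixture_split()$test_idx)
  pick <- tr_idx[c(1, 25, 50)]
  pred <- predict_exercise(model, feat$X[pick, , drop = FALSE])
  expect_equal(as.character(pred$label), feat$y[pick])
  # held-out repetitions are also recognized
  te <- fixture_split()$test_idx
  pte <- predict_exercise(model, feat$X[te, , drop = FALSE])
  expect_gte(mean(as.character(pte$label) == feat$y[te]), 0.99)
  expect_error(predict_exercise(model, numeric(10)), "mismatch")
  z <- predict_exercise(model, rep(0, 285))
  expect_s3_class(z$label, "factor")
})

test_that("model bundles survive a save/load round trip", {
  model <- fixture_model()
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$classifier, model$classifier)
  feat <- fixture_features()
  p1 <- predict_exercise(model, feat$X[1, ])
  p2 <- predict_exercise(back, feat$X[1, ])
  expect_identical(as.character(p1$label), as.character(p2$label))
  unlink(path)
})

test_that("permuted labels collapse accuracy to chance", {
  feat <- fixture_features()
  set.seed(99)
  yp <- sample(feat$y)
  repp <- train_and_evaluate(feat$X, yp, feat$subjects, fixture_split(),
                             use_pca = TRUE, cv_folds = 0, seed = 1)
  acc <- repp$metrics$accuracy[repp$metrics$classifier == "SVML"]
  expect_gt(acc, 5); expect_lt(acc, 40)
})
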