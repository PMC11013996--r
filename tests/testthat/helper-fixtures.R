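# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

# small labelled corpus + trained model bundle (used by recognition and
# session tests)
fixture_model <- function() {
  if (is.null(.fixture_cache$model)) {
    trials <- make_dataset(8, reps_per_exercise = 4, seed = 1)
    feat <- corpus_features(trials)
    split <- split_by_subject(feat$subjects, 0.30, seed = 7)
    rep <- train_and_evaluate(feat$X, feat$y, feat$subjects, split,
                              use_pca = TRUE, cv_folds = 0, seed = 1)
    .fixture_cache$feat <- feat
    .fixture_cache$split <- split
    .fixture_cache$report <- rep
    .fixture_cache$model <- rep$model
  }
  .fixture_cache$model
}

fixture_features <- function() { fixture_model(); .fixture_cache$feat }
fixture_report <- function() { fixture_model(); .fixture_cache$report }
fixture_split <- function() { fixture_model(); .fixture_cache$split }

# one clean single-phase trial
sim_trial <- function(exercise, rom_deg, period_s, n_reps = 5,
                      noise_sd = 0.003, seed = 1, errors = character(0),
                      fps = 30, drift_sd = 0, ...) {
  simulate_motion(motion_script(list(
    motion_phase(exercise, rom_deg = rom_deg, period_s = period_s,
                 n_reps = n_reps, errors = errors, ...)
  ), fps = fps, noise_sd = noise_sd, drift_sd = drift_sd, seed = seed))
}

# a neutral standing frame built from the generator
standing_frame <- function() {
  sim <- simulate_motion(motion_script(list(
    motion_phase("idle", duration_s = 0.2)), noise_sd = 0, seed = 1))
  get_frame(sim$seq, 1)
}

# independent atan2-based angle oracle (cross/dot formulation)
atan2_angle <- function(a, b, c) {
  u <- a[1:2] - b[1:2]; v <- c[1:2] - b[1:2]
  abs(atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))) * 180 / pi
}

# direct-formula oracles for the 12 time-domain features
oracle_time_features <- function(x) {
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  rms <- sqrt(sum(x^2) / n)
  c(mean = m, max = max(x), min = min(x), rms = rms, variance = m2,
    std = sqrt(m2), crest = if (rms < 1e-24) 1 else max(abs(x)) / rms,
    kurtosis = if (m2 < 1e-24) 0 else m4 / m2^2 - 3,
    skewness = if (m2 < 1e-24) 0 else m3 / m2^1.5,
    median = stats::median(x), p2p = max(x) - min(x), energy = sum(x^2))
}
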