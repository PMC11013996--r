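#' @title Exercise recognition: features, PCA and classifiers
#' @description
#' Per-repetition descriptor pipeline: five basic body keypoints (torso and
#' the distal end of each limb) give 15 coordinate time series; 12
#' time-domain plus 7 frequency-domain features per series give a 285-value
#' vector; optional PCA keeps the leading components explaining 90\% of the
#' variance; random forest, three SVM kernels and a decision tree are
#' trained and compared with subject-wise train/test splits and k-fold
#' cross-validation.
#' @name recognition
NULL

FEATURE_ROLES <- c("torso", "left_arm", "right_arm", "left_leg", "right_leg")
TIME_FEATURES <- c("mean", "max", "min", "rms", "variance", "std", "crest",
                   "kurtosis", "skewness", "median", "p2p", "energy")
FREQ_FEATURES <- c("bp_mean", "bp_max", "bp_sum", "bp_std", "bp_peakf",
                   "bp_kurtosis", "bp_skewness")

#' Default basic keypoint set
#'
#' Five body regions reduced to one keypoint each: the torso as the virtual
#' mid-hip point (mean of the two hip landmarks), the arms as the wrists
#' and the legs as the ankles -- distal points carry the largest motion
#' amplitude.
#'
#' @param torso,left_arm,right_arm,left_leg,right_leg 0-based landmark ids;
#'   \code{torso = NA} selects the virtual mid-hip point.
#' @export
basic_keypoint_set <- function(torso = NA,
                               left_arm = BLAZEPOSE[["left_wrist"]],
                               right_arm = BLAZEPOSE[["right_wrist"]],
                               left_leg = BLAZEPOSE[["left_ankle"]],
                               right_leg = BLAZEPOSE[["right_ankle"]]) {
  structure(list(torso = torso, left_arm = left_arm, right_arm = right_arm,
                 left_leg = left_leg, right_leg = right_leg),
            class = "basic_keypoint_set")
}

#' Select the 15 basic-keypoint signals
#'
#' x, y and z traces for each of the five basic keypoints, in fixed
#' (role, axis) order.
#'
#' @param ss a \code{signal_set} from \code{\link{extract_signals}}.
#' @param bset a \code{basic_keypoint_set}.
#' @return Named list of 15 \code{motion_signal} ("role_axis").
#' @export
select_basic_signals <- function(ss, bset = basic_keypoint_set()) {
  stopifnot(inherits(ss, "signal_set"))
  out <- list()
  for (role in FEATURE_ROLES) {
    id <- bset[[role]]
    for (axis in AXES) {
      nm <- paste0(role, "_", axis)
      if (role == "torso" && is.na(id)) {
        v <- (ss$signals[[paste0("k23_", axis)]]$values +
                ss$signals[[paste0("k24_", axis)]]$values) / 2
        out[[nm]] <- motion_signal(v, ss$fs, label = c("midhip", axis))
      } else {
        out[[nm]] <- ss$signals[[paste0("k", id, "_", axis)]]
      }
    }
  }
  out
}

# population moments; skew/kurtosis fall back to 0 for (near-)constant input
moment_skewness <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 < 1e-24) return(0)
  mean((x - m)^3) / m2^1.5
}
moment_kurtosis <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 < 1e-24) return(0)
  mean((x - m)^4) / m2^2 - 3
}

#' One-sided band power spectrum (periodogram)
#'
#' Hann-windowed periodogram of the mean-centered signal over the full
#' \code{[0, fs/2]} band.
#'
#' @param x numeric vector (length >= 8).
#' @param fs sampling rate.
#' @return List with \code{$freq} (Hz) and \code{$power}.
#' @export
band_power_spectrum <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 8)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)   # Hann window
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  half <- seq_len(floor(n / 2) + 1L)
  p <- Mod(X[half])^2 / (fs * sum(w^2))
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(half)] <- 1
  list(freq = (half - 1L) * fs / n, power = p * scale2)
}

feature_block <- function(x, fs) {
  m <- mean(x)
  rms <- sqrt(mean(x^2))
  vr <- mean((x - m)^2)
  bp <- band_power_spectrum(x, fs)
  p <- bp$power
  c(
    mean = m, max = max(x), min = min(x), rms = rms, variance = vr,
    std = sqrt(vr), crest = if (rms < 1e-24) 1 else max(abs(x)) / rms,
    kurtosis = moment_kurtosis(x), skewness = moment_skewness(x),
    median = stats::median(x), p2p = max(x) - min(x), energy = sum(x^2),
    bp_mean = mean(p), bp_max = max(p), bp_sum = sum(p),
    bp_std = stats::sd(p), bp_peakf = bp$freq[which.max(p)],
    bp_kurtosis = moment_kurtosis(p), bp_skewness = moment_skewness(p)
  )
}

#' Extract the 285-value feature vector of one repetition
#'
#' 12 time-domain features (mean, max, min, RMS, variance, standard
#' deviation, crest factor, kurtosis, skewness, median, peak-to-peak,
#' energy) and 7 band-power features (mean, max, total, standard deviation,
#' peak frequency, kurtosis, skewness of the periodogram) per signal:
#' 19 x 15 = 285 values in a fixed, stable order.
#'
#' @param signals the 15 basic-keypoint signals (list from
#'   \code{\link{select_basic_signals}}), each of length >= 8.
#' @param fs sampling rate for bare vectors.
#' @return Named numeric vector of length 285
#'   ("role_axis_feature").
#' @export
extract_features <- function(signals, fs = NULL) {
  stopifnot(length(signals) == 15L)
  out <- numeric(0)
  for (nm in names(signals)) {
    x <- sig_values(signals[[nm]])
    f <- sig_fs(signals[[nm]], fs)
    if (length(x) < 8) stop("signal ", nm, " too short (need >= 8 samples)")
    blk <- feature_block(x, f)
    names(blk) <- paste0(nm, "_", names(blk))
    out <- c(out, blk)
  }
  if (any(!is.finite(out))) stop("non-finite feature value")
  stopifnot(length(out) == 285L)
  out
}

# ---------------------------------------------------------------------------
# PCA
# ---------------------------------------------------------------------------

#' Fit PCA on a standardized feature matrix
#'
#' Columns are z-scored (features live on wildly different scales) and the
#' smallest leading set of principal components whose cumulative explained
#' variance reaches \code{target_var} is retained.
#'
#' @param X numeric matrix, rows = repetitions, columns = features.
#' @param target_var cumulative explained-variance target (default 0.90).
#' @return A \code{pca_model}: \code{$center}, \code{$scale},
#'   \code{$rotation} (columns = retained components), \code{$var_frac}
#'   (all components), \code{$n_retained}.
#' @export
fit_pca <- function(X, target_var = 0.90) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl < 1e-12)) stop("degenerate feature matrix: zero variance")
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  n_ret <- which(cumsum(var_frac) >= target_var)[1]
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(n_ret), drop = FALSE],
                 var_frac = var_frac, n_retained = n_ret,
                 target_var = target_var),
            class = "pca_model")
}

#' Project feature rows into a fitted PCA space
#' @param model a \code{pca_model}.
#' @param X feature matrix (or single vector) in the original 285-space.
#' @export
transform_pca <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Z <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
  Z %*% model$rotation
}

# ---------------------------------------------------------------------------
# Subject-wise splitting, training, evaluation
# ---------------------------------------------------------------------------

#' Subject-wise train/test split
#'
#' Whole subjects are drawn (without replacement, in seeded random order)
#' into the test set until its repetition count is nearest the target
#' fraction of all records, so no individual ever straddles the split.
#'
#' @param subjects subject id per repetition.
#' @param test_fraction target fraction of records in the test set
#'   (default 0.30).
#' @param seed RNG seed.
#' @return List with \code{$train_subjects}, \code{$test_subjects},
#'   \code{$test_idx} (row indices) and \code{$achieved_fraction}.
#' @export
split_by_subject <- function(subjects, test_fraction = 0.30, seed = 1) {
  ids <- unique(subjects)
  if (length(ids) < 2) stop("need at least 2 subjects for a subject-wise split")
  set.seed(seed)
  shuffled <- sample(ids)
  counts <- vapply(shuffled, function(s) sum(subjects == s), numeric(1))
  cum <- cumsum(counts)
  target <- test_fraction * length(subjects)
  k <- which.min(abs(cum - target))
  k <- max(1L, min(k, length(ids) - 1L))
  test_ids <- shuffled[seq_len(k)]
  list(train_subjects = setdiff(ids, test_ids), test_subjects = test_ids,
       test_idx = which(subjects %in% test_ids),
       achieved_fraction = cum[k] / length(subjects))
}

CLASSIFIERS <- c("RF", "SVML", "SVMP", "SVMRBF", "DT")

fit_one <- function(kind, X, y, seed) {
  set.seed(seed)
  df <- data.frame(X)
  df$.y <- y
  switch(kind,
    RF = randomForest::randomForest(x = X, y = y, ntree = 100),
    SVML = e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE),
    SVMP = e1071::svm(X, y, kernel = "polynomial", degree = 3, cost = 1,
                      scale = FALSE),
    SVMRBF = e1071::svm(X, y, kernel = "radial", cost = 1, scale = FALSE),
    DT = rpart::rpart(.y ~ ., data = df, method = "class")
  )
}

predict_one <- function(kind, fit, X) {
  if (kind == "DT") {
    cls <- colnames(stats::predict(fit, data.frame(X)))
    factor(cls[apply(stats::predict(fit, data.frame(X)), 1, which.max)],
           levels = fit$ylevels %||% cls)
  } else stats::predict(fit, X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification metrics from truth/prediction labels
#'
#' Accuracy plus macro-averaged F1, precision, sensitivity and specificity,
#' all in percent, with the confusion matrix (rows = truth) and per-class
#' accuracy.
#'
#' @param truth,pred factors on the same levels.
#' @export
classification_metrics <- function(truth, pred) {
  lev <- levels(truth)
  pred <- factor(pred, levels = lev)
  C <- table(truth = truth, pred = pred)
  tot <- sum(C)
  per <- vapply(seq_along(lev), function(k) {
    tp <- C[k, k]; fn <- sum(C[k, ]) - tp; fp <- sum(C[, k]) - tp
    tn <- tot - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    c(prec = prec, sens = sens, spec = spec, f1 = f1,
      acc = if (sum(C[k, ]) > 0) tp / sum(C[k, ]) else NA_real_)
  }, numeric(5))
  list(
    accuracy = 100 * sum(diag(C)) / tot,
    f1 = 100 * mean(per["f1", ]),
    precision = 100 * mean(per["prec", ]),
    sensitivity = 100 * mean(per["sens", ]),
    specificity = 100 * mean(per["spec", ]),
    per_class_accuracy = stats::setNames(100 * per["acc", ], lev),
    confusion = C
  )
}

#' Train and evaluate the classifier battery
#'
#' Standardizes features on the training rows only, optionally fits PCA
#' (also on train only), trains RF, SVM (linear / polynomial / RBF) and a
#' decision tree, and reports held-out test metrics, per-class accuracy,
#' confusion matrices, train/inference timing and (optionally) k-fold
#' cross-validated accuracy on the training set.  Subject leakage between
#' train and test is asserted inside this function, not only in the split
#' constructor.
#'
#' @param X feature matrix (rows = repetitions, 285 columns).
#' @param y exercise labels (coerced to factor on the repertoire levels).
#' @param subjects subject id per row.
#' @param split a split from \code{\link{split_by_subject}}.
#' @param use_pca reduce dimensionality before training (default TRUE).
#' @param cv_folds folds for train-set cross-validation; 0 skips CV.
#' @param seed RNG seed for every randomized element.
#' @param target_var PCA explained-variance target.
#' @return A \code{classifier_report}: per-classifier metrics
#'   (\code{$metrics} data.frame), \code{$confusion}, \code{$cv_accuracy},
#'   \code{$best} (highest test accuracy) and \code{$model} (a deployable
#'   bundle for \code{\link{predict_exercise}}).
#' @export
train_and_evaluate <- function(X, y, subjects, split, use_pca = TRUE,
                               cv_folds = 10, seed = 1, target_var = 0.90) {
  X <- as.matrix(X)
  lev <- names(EXERCISES)[names(EXERCISES) %in% unique(as.character(y))]
  y <- factor(as.character(y), levels = lev)
  te <- split$test_idx
  tr <- setdiff(seq_len(nrow(X)), te)
  if (length(intersect(subjects[tr], subjects[te])) > 0)
    stop("subject leakage: a test subject appears in the training set")
  if (!all(lev %in% unique(as.character(y[tr]))))
    stop("class missing from training set")
  ctr <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-12] <- 1
  std <- function(M) sweep(sweep(M, 2, ctr), 2, scl, "/")
  pca <- NULL
  prep <- function(M) {
    Z <- std(M)
    if (!is.null(pca)) Z %*% pca$rotation else Z
  }
  if (use_pca) {
    pca_full <- fit_pca(X[tr, , drop = FALSE], target_var = target_var)
    pca <- list(rotation = pca_full$rotation,
                n_retained = pca_full$n_retained,
                var_frac = pca_full$var_frac)
  }
  Xtr <- prep(X[tr, , drop = FALSE]); ytr <- y[tr]
  Xte <- prep(X[te, , drop = FALSE]); yte <- y[te]
  metrics <- list(); confusion <- list(); cvacc <- rep(NA_real_, length(CLASSIFIERS))
  names(cvacc) <- CLASSIFIERS
  fits <- list()
  for (kind in CLASSIFIERS) {
    tt <- system.time(fit <- fit_one(kind, Xtr, ytr, seed))[["elapsed"]]
    it <- system.time(pred <- predict_one(kind, fit, Xte))[["elapsed"]]
    m <- classification_metrics(yte, pred)
    metrics[[kind]] <- data.frame(
      classifier = kind, accuracy = m$accuracy, f1 = m$f1,
      precision = m$precision, sensitivity = m$sensitivity,
      specificity = m$specificity, train_time_s = tt, infer_time_s = it
    )
    confusion[[kind]] <- m$confusion
    fits[[kind]] <- fit
    if (cv_folds > 1) {
      set.seed(seed)
      folds <- sample(rep_len(seq_len(cv_folds), length(ytr)))
      hits <- 0L
      for (f in seq_len(cv_folds)) {
        inF <- folds == f
        if (length(unique(ytr[!inF])) < length(lev)) next
        ff <- fit_one(kind, Xtr[!inF, , drop = FALSE], ytr[!inF], seed + f)
        hits <- hits + sum(predict_one(kind, ff, Xtr[inF, , drop = FALSE]) ==
                             ytr[inF])
      }
      cvacc[kind] <- 100 * hits / length(ytr)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  best <- metrics$classifier[which.max(metrics$accuracy)]
  per_class <- classification_metrics(
    yte, predict_one(best, fits[[best]], Xte))$per_class_accuracy
  bundle <- structure(list(
    classifier = best, fit = fits[[best]], center = ctr, scale = scl,
    pca = pca, levels = lev, n_features = ncol(X),
    feature_names = colnames(X), version = "1"
  ), class = "kinerehab_model")
  structure(list(metrics = metrics, confusion = confusion,
                 cv_accuracy = cvacc, per_class_accuracy = per_class,
                 best = best, model = bundle,
                 split = split, use_pca = use_pca),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> best:", x$best, "\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Predict the exercise of one feature vector
#'
#' @param model a deployable bundle (\code{$model} of a
#'   \code{classifier_report}).
#' @param fv a 285-value feature vector (or matrix of rows).
#' @return List with \code{$label} (factor) and \code{$score} (winning
#'   class vote / probability in [0, 1]).
#' @export
predict_exercise <- function(model, fv) {
  stopifnot(inherits(model, "kinerehab_model"))
  M <- if (is.null(dim(fv))) matrix(fv, nrow = 1) else as.matrix(fv)
  if (ncol(M) != model$n_features)
    stop("feature dimension mismatch: got ", ncol(M), ", expected ",
         model$n_features)
  Z <- sweep(sweep(M, 2, model$center), 2, model$scale, "/")
  if (!is.null(model$pca)) Z <- Z %*% model$pca$rotation
  kind <- model$classifier
  pred <- predict_one(kind, model$fit, Z)
  score <- rep(NA_real_, nrow(Z))
  if (kind == "RF") {
    v <- stats::predict(model$fit, Z, type = "vote")
    score <- apply(v, 1, max)
  } else if (kind == "DT") {
    p <- stats::predict(model$fit, data.frame(Z))
    score <- apply(p, 1, max)
  } else {
    dv <- attr(stats::predict(model$fit, Z, decision.values = TRUE),
               "decision.values")
    if (!is.null(dv)) score <- 1 / (1 + exp(-apply(abs(dv), 1, max)))
  }
  list(label = factor(as.character(pred), levels = model$levels),
       score = as.numeric(score))
}

#' Save / load a deployable model bundle
#'
#' The bundle (scaler + optional PCA + classifier + feature specification +
#' version) round-trips through a single RDS archive; loading refuses a
#' bundle whose feature specification does not match the current extractor.
#'
#' @param model a \code{kinerehab_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kinerehab_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "kinerehab_model"))
    stop("not a kinerehab model bundle")
  if (model$n_features != 285L)
    stop("feature-spec mismatch: bundle has ", model$n_features,
         " features, extractor produces 285")
  model
}
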