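#' @title Motion time-series preparation
#' @description
#' Preprocessing chain for keypoint signals: percentage amplitude
#' modulation and motion/pause detection, singular spectrum analysis (SSA)
#' detrending for hand-held camera drift, moving-average smoothing, period
#' estimation and repetition-based segmentation.
#' @name signal_prep
NULL

sig_values <- function(sig) if (inherits(sig, "motion_signal")) sig$values else as.numeric(sig)
sig_fs <- function(sig, fs = NULL) {
  if (inherits(sig, "motion_signal")) sig$fs
  else if (!is.null(fs)) fs
  else stop("fs required for bare numeric signals")
}

#' Percentage amplitude modulation between consecutive samples
#'
#' \code{m[i] = 100 * |x[i+1] - x[i]| / max(|x[i]|, eps)}: the per-sample
#' relative amplitude change, in percent.  The denominator is floored at
#' \code{eps} so that samples near zero do not blow up the ratio.
#'
#' @param sig a \code{motion_signal} or numeric vector, length >= 2.
#' @param eps denominator floor in signal units (default 1e-3, i.e. one
#'   thousandth of the image extent for normalized coordinates).
#' @return Numeric vector of length \code{n - 1}, in percent.
#' @export
amplitude_modulation <- function(sig, eps = 1e-3) {
  x <- sig_values(sig)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  100 * abs(diff(x)) / pmax(abs(x[-n]), eps)
}

#' Detect activity and pause segments
#'
#' Splits a signal into alternating active/pause segments.  The signal is
#' median-centered and lightly smoothed; a sample is scored active when,
#' within a centered sliding window, (a) the fraction of modulation values
#' exceeding \code{threshold_pct} reaches \code{vote_frac} and (b) the local
#' signal range exceeds \code{amp_min} (an absolute motion floor that keeps
#' estimation noise on a resting subject from registering as activity).
#' Runs shorter than \code{min_active_s} / \code{min_pause_s} are merged
#' into their neighbours, so the result is a debounced partition of
#' \code{[0, n)}.
#'
#' @param sig \code{motion_signal} (or numeric + \code{fs}).
#' @param threshold_pct modulation threshold in percent (default 30).
#' @param min_active_s,min_pause_s minimum segment durations (defaults 0.5
#'   and 1.0 s).
#' @param window_s sliding vote window (default 0.5 s).
#' @param vote_frac fraction of above-threshold modulation samples needed in
#'   the window (default 0.1).
#' @param amp_min minimum local peak-to-peak amplitude, normalized units.
#' @param fs sampling rate when \code{sig} is a bare vector.
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open sample indices) and \code{kind} ("active"/"pause").
#' @export
detect_activity <- function(sig, threshold_pct = 30, min_active_s = 0.5,
                            min_pause_s = 1.0, window_s = 0.5,
                            vote_frac = 0.1, amp_min = 0.01, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  xc <- x - stats::median(x)
  xs <- moving_average(xc, M = max(1L, round(fs / 10)), fs = fs)$values
  eps <- max(1e-3, 0.05 * max(abs(xs)))
  m <- amplitude_modulation(motion_signal(xs, fs), eps = eps)
  hot <- c(m > threshold_pct, FALSE)          # pad to length n
  W <- max(1L, round(window_s * fs / 2))      # half window in samples
  active <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - W); hi <- min(n, i + W)
    frac <- mean(hot[lo:hi])
    rng <- diff(range(xs[lo:hi]))
    active[i] <- frac >= vote_frac && rng >= amp_min
  }
  runs <- rle(active)
  # debounce: absorb short runs into neighbours, iterating to a fixed point
  repeat {
    len_s <- runs$lengths / fs
    min_s <- ifelse(runs$values, min_active_s, min_pause_s)
    short <- which(len_s < min_s & length(runs$lengths) > 1)
    if (!length(short)) break
    j <- short[which.min(len_s[short])]
    runs$values[j] <- !runs$values[j]
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts, end = ends,
             kind = ifelse(runs$values, "active", "pause"),
             stringsAsFactors = FALSE)
}

#' Moving-average smoothing
#'
#' Centered window mean \code{mean(x[i-M .. i+M])}; at the boundaries the
#' window shrinks to the available samples, so the output has the input's
#' length.  \code{M = 0} is the identity.
#'
#' @param sig \code{motion_signal} or numeric vector.
#' @param M half-window in samples (>= 0).
#' @param fs sampling rate for bare vectors.
#' @return A \code{motion_signal} of the same length.
#' @export
moving_average <- function(sig, M, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  stopifnot(M >= 0)
  n <- length(x)
  if (M == 0 || n == 1) return(motion_signal(x, fs,
    label = if (inherits(sig, "motion_signal")) sig$label else c(NA, NA)))
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - M); hi <- pmin(n, i + M)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  motion_signal(out, fs,
    label = if (inherits(sig, "motion_signal")) sig$label else c(NA, NA))
}

# ---------------------------------------------------------------------------
# Singular spectrum analysis
# ---------------------------------------------------------------------------

#' Singular spectrum analysis decomposition
#'
#' Classical SSA: embed the series into an L x K trajectory matrix of
#' lagged windows, take its singular value decomposition, reconstruct one
#' elementary series per rank-1 term by anti-diagonal averaging, and keep
#' \code{n_components} of them (ordered by decreasing singular value; any
#' residual energy beyond the first \code{n_components - 1} terms is folded
#' into the last component so the components sum to the input exactly).
#' The components are then grouped into trend, periodicity and noise:
#' trend = components whose dominant discrete frequency is below
#' \code{f_trend} Hz; noise = components carrying less than \code{e_noise}
#' of the total energy; periodic = the rest.
#'
#' @param sig \code{motion_signal} or numeric vector with \code{fs}.
#' @param L embedding window length (samples); default
#'   \code{min(floor(n/2), round(2 * fs * expected_period))}.
#' @param n_components number of summable components (default 12).
#' @param f_trend trend cutoff frequency in Hz (default 0.1).
#' @param e_noise noise energy fraction threshold (default 0.01).
#' @param expected_period seconds, used only for the default L (default 2).
#' @param fs sampling rate for bare vectors.
#' @return An object of class \code{ssa_decomposition}: \code{$components}
#'   (n_components x n matrix), \code{$trend}, \code{$periodic},
#'   \code{$noise} (grouped reconstructions), \code{$groups}, \code{$window}.
#' @export
ssa_decompose <- function(sig, L = NULL, n_components = 12, f_trend = 0.1,
                          e_noise = 0.01, expected_period = 2, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  if (any(!is.finite(x))) stop("non-finite values in signal")
  n <- length(x)
  if (is.null(L)) L <- max(2L, min(floor(n / 2), round(2 * fs * expected_period)))
  L <- as.integer(L)
  if (n <= L) stop("signal length (", n, ") must exceed window L (", L, ")")
  if (L < 2) stop("window L must be >= 2")
  if (n_components > L) stop("n_components must be <= L")
  K <- n - L + 1L
  X <- matrix(0, L, K)
  for (j in seq_len(K)) X[, j] <- x[j:(j + L - 1L)]
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  keep <- min(n_components - 1L, r)
  comps <- matrix(0, n_components, n)
  recon_one <- function(u, d, v) diag_average(d * tcrossprod(u, v))
  for (k in seq_len(keep))
    comps[k, ] <- recon_one(sv$u[, k], sv$d[k], sv$v[, k])
  # residual of everything beyond the first keep terms, folded into the last
  comps[n_components, ] <- comps[n_components, ] + (x - colSums(comps))
  energy <- rowSums(comps^2)
  efrac <- energy / max(sum(energy), .Machine$double.eps)
  domf <- apply(comps, 1, dominant_frequency, fs = fs)
  # a component slower than the spectral resolution can only show up in the
  # first nonzero bin; treat anything at or below that bin as trend too.
  # Trend components are claimed before the energy gate so that the small
  # secondary terms of a slow baseline still end up subtracted with it.
  f_cut <- max(f_trend, 1.5 * fs / n)
  group <- ifelse(domf < f_cut & efrac >= 1e-4, "trend",
                  ifelse(efrac < e_noise, "noise", "periodic"))
  pick <- function(g) {
    rows <- which(group == g)
    if (!length(rows)) numeric(n) else colSums(comps[rows, , drop = FALSE])
  }
  structure(list(
    components = comps, trend = pick("trend"), periodic = pick("periodic"),
    noise = pick("noise"), groups = group, window = L, fs = fs
  ), class = "ssa_decomposition")
}

# anti-diagonal (Hankel) averaging of an L x K matrix into a series of
# length L + K - 1
diag_average <- function(M) {
  L <- nrow(M); K <- ncol(M)
  n <- L + K - 1L
  idx <- row(M) + col(M) - 1L
  sums <- tapply(M, idx, sum)
  cnt <- tabulate(idx, nbins = n)
  as.numeric(sums) / cnt
}

dominant_frequency <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  if (all(abs(xc) < 1e-14)) return(0)
  p <- Mod(stats::fft(xc))^2
  half <- seq_len(floor(n / 2) + 1L)
  freqs <- (half - 1L) * fs / n
  freqs[which.max(p[half])]
}

#' Remove the SSA trend from a signal
#'
#' Subtracts the reconstructed trend component (camera drift and other slow
#' baseline movement) from the original signal.  Intended for hand-held
#' recordings; fixed-camera signals can skip it.
#'
#' @param sig the original \code{motion_signal} (or numeric + \code{fs}).
#' @param ssa its \code{ssa_decomposition} (computed from \code{sig}).
#' @param fs sampling rate for bare vectors.
#' @return A detrended \code{motion_signal}.
#' @export
detrend <- function(sig, ssa = NULL, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  if (is.null(ssa)) ssa <- ssa_decompose(motion_signal(x, fs))
  stopifnot(inherits(ssa, "ssa_decomposition"))
  if (length(ssa$trend) != length(x))
    stop("length mismatch between signal and decomposition")
  motion_signal(x - ssa$trend, fs,
    label = if (inherits(sig, "motion_signal")) sig$label else c(NA, NA))
}

# ---------------------------------------------------------------------------
# Period estimation and repetition segmentation
# ---------------------------------------------------------------------------

#' Estimate the repetition period of a quasi-periodic signal
#'
#' Lag of the first autocorrelation peak inside \code{[min_period,
#' max_period]} whose height clears \code{min_acf}; the repetition duration
#' of the exercise driving the signal.
#'
#' @param sig \code{motion_signal} or numeric + \code{fs}.
#' @param min_period,max_period search range in seconds (defaults 0.5, 10).
#' @param min_acf minimum normalized autocorrelation at the peak
#'   (default 0.2).
#' @param fs sampling rate for bare vectors.
#' @return Period in seconds.
#' @export
estimate_period <- function(sig, min_period = 0.5, max_period = 10,
                            min_acf = 0.2, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  n <- length(x)
  xc <- x - mean(x)
  if (stats::sd(x) < 1e-12) stop("aperiodic signal: no phase information")
  max_lag <- min(n - 2L, ceiling(max_period * fs), floor(n / 2))
  ac <- stats::acf(xc, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # symmetric smoothing so noise wiggles on the flanks do not masquerade as
  # peaks (a centered window leaves a symmetric peak's position untouched)
  acs <- ac
  if (length(ac) > 9) {
    Msm <- max(1L, round(fs / 15))
    acs <- moving_average(ac, Msm, fs = 1)$values
  }
  lags <- seq_along(ac) - 1L
  n_ac <- length(xc)
  # undo the 1/n acf taper's leftward bias (bounded so long-lag noise does
  # not explode)
  acs <- acs / pmax((n_ac - lags) / n_ac, 0.5)
  lo <- max(2L, floor(min_period * fs))
  cand <- which(lags >= lo & lags <= max_lag)
  if (!length(cand) || max(acs[cand]) < min_acf)
    stop("aperiodic signal: no autocorrelation peak found")
  # among near-maximal band peaks take the smallest lag: the fundamental
  # beats its multiples, while sub-maximal noise wiggles are ignored
  big <- cand[acs[cand] >= 0.85 * max(acs[cand]) & acs[cand] >= min_acf]
  pk <- big[c(TRUE, diff(big) > 1)][1]
  first <- (pk - 1L) + which.max(acs[pk:min(pk + max(2L, lo), length(acs))])
  ac <- acs
  # parabolic refinement around the discrete peak
  if (first > 1 && first < length(ac)) {
    y1 <- ac[first - 1L]; y2 <- ac[first]; y3 <- ac[first + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  (lags[first] + delta) / fs
}

#' Detect the first completed movement cycle of a signal
#'
#' Finds the earliest rest-to-rest lobe: a pair of consecutive low-valued
#' minima enclosing an excursion of at least half the signal's range, with
#' duration inside \code{[min_s, max_s]}.  Unlike
#' \code{\link{segment_repetitions}} it needs no period estimate, so it can
#' fire as soon as a single execution period has elapsed -- the live
#' recognizer's trigger.
#'
#' @param sig \code{motion_signal} or numeric + \code{fs}.
#' @param min_s,max_s admissible cycle duration in seconds.
#' @param fs sampling rate for bare vectors.
#' @return List with \code{start}, \code{end} (0-based half-open) and
#'   \code{duration} (s), or NULL when no completed cycle exists yet.
#' @export
first_cycle <- function(sig, min_s = 0.8, max_s = 10, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  n <- length(x)
  if (n < max(8, min_s * fs)) return(NULL)
  xs <- moving_average(x, M = max(1L, round(fs / 10)), fs = fs)$values
  rng <- range(xs)
  if (diff(rng) < 1e-9) return(NULL)
  if (xs[1] - rng[1] > 0.5 * diff(rng)) { xs <- -xs; rng <- range(xs) }
  low <- rng[1] + 0.35 * diff(rng)
  interior <- which(diff(sign(diff(xs))) > 0) + 1L
  cand <- sort(unique(c(1L, interior, n)))
  cand <- cand[xs[cand] <= low]
  if (length(cand) < 2) return(NULL)
  merged <- cand[1]
  for (c0 in cand[-1]) {
    last <- merged[length(merged)]
    if ((c0 - last) / fs < min_s / 2) {
      if (xs[c0] < xs[last]) merged[length(merged)] <- c0
    } else merged <- c(merged, c0)
  }
  if (length(merged) < 2) return(NULL)
  for (i in seq_len(length(merged) - 1L)) {
    a <- merged[i]; b <- merged[i + 1L]
    dur <- (b - a) / fs
    if (dur < min_s || dur > max_s) next
    span <- diff(stats::quantile(xs[a:b], c(0.02, 0.98), names = FALSE))
    if (span >= 0.5 * diff(rng))
      return(list(start = a - 1L, end = b - 1L, duration = dur))
  }
  NULL
}

#' Segment a signal into repetitions
#'
#' Cuts the (smoothed) signal at successive local minima spaced roughly one
#' period apart.  Boundary candidates are minima lying in the bottom part of
#' the signal's range (all five exercise angle profiles return to the rest
#' posture between repetitions); consecutive candidate pairs whose spacing
#' falls within \code{[0.5, 1.5]} periods become repetition segments, so a
#' trailing half-executed repetition is dropped rather than reported.
#'
#' @param sig \code{motion_signal} or numeric + \code{fs}; the active
#'   portion of the dominant movement signal.
#' @param period repetition period in seconds (> 0).
#' @param low_frac boundary values must lie within this fraction of the
#'   range above the minimum (default 0.35).
#' @param fs sampling rate for bare vectors.
#' @return data.frame with \code{start}, \code{end} (0-based half-open
#'   sample indices) and \code{duration} (seconds); zero rows when the
#'   period exceeds the signal.
#' @export
segment_repetitions <- function(sig, period, low_frac = 0.35, fs = NULL) {
  x <- sig_values(sig)
  fs <- sig_fs(sig, fs)
  stopifnot(period > 0)
  n <- length(x)
  empty <- data.frame(start = integer(0), end = integer(0),
                      duration = numeric(0))
  P <- period * fs
  if (n < 0.75 * P || n < 4) return(empty)
  xs <- moving_average(x, M = max(1L, round(P / 20)), fs = fs)$values
  rng <- range(xs)
  if (diff(rng) < 1e-12) return(empty)
  # orient so the rest posture (segment start) sits at the signal minimum
  if (xs[1] - rng[1] > 0.5 * diff(rng)) {
    xs <- -xs
    rng <- range(xs)
  }
  low <- rng[1] + low_frac * diff(rng)
  interior <- which(diff(sign(diff(xs))) > 0) + 1L    # local minima
  cand <- sort(unique(c(1L, interior, n)))
  cand <- cand[xs[cand] <= low]
  if (length(cand) < 2) return(empty)
  # collapse clusters of near-by candidates (closer than half a period)
  merged <- cand[1]
  for (c0 in cand[-1]) {
    last <- merged[length(merged)]
    if (c0 - last < 0.5 * P) {
      if (xs[c0] < xs[last]) merged[length(merged)] <- c0
    } else merged <- c(merged, c0)
  }
  if (length(merged) < 2) return(empty)
  b <- merged - 1L                       # 0-based boundaries
  if (b[length(b)] == n - 1L) b[length(b)] <- n   # half-open end of trace
  starts <- b[-length(b)]
  ends <- b[-1]
  dur <- (ends - starts) / fs
  ok <- dur >= 0.5 * period & dur <= 1.5 * period
  # amplitude gate: a repetition must actually sweep the movement's range,
  # which rejects quiet stretches between minima (e.g. a trailing pause)
  span <- vapply(seq_along(starts), function(i) {
    seg <- xs[(starts[i] + 1L):min(ends[i], n)]
    diff(stats::quantile(seg, c(0.02, 0.98), names = FALSE))
  }, numeric(1))
  ok <- ok & span >= 0.3 * diff(rng)
  data.frame(start = starts[ok], end = ends[ok], duration = dur[ok])
}
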