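#' Default prominent-point search windows
#'
#' Canonical auditory ERP deflection windows: Pa 25-35 ms, P1 60-80 ms,
#' N1 90-110 ms, P2 150-250 ms (post-stimulus). N1 is a negative deflection
#' and is located by the window minimum; the others by the maximum.
#' @return Named list of `c(lo, hi)` ms pairs.
#' @export
default_prominent_windows <- function() {
  list(Pa = c(25, 35), P1 = c(60, 80), N1 = c(90, 110), P2 = c(150, 250))
}

#' Default EEG rhythm bands
#'
#' Standard clinical band edges in Hz: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30.
#' @return Named list of `c(lo, hi)` Hz pairs.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Detect prominent ERP points
#'
#' Finds the four canonical deflections in their search windows. Pa, P1 and
#' P2 are the window maxima, N1 the window minimum (set `n1_negative = FALSE`
#' to treat N1 as a maximum as well). Ties break toward the earliest latency.
#' Each point also carries the mean amplitude over its window.
#'
#' @param erp An [erp_waveform()] covering at least the last window's end.
#' @param windows Named list of `c(lo, hi)` ms windows.
#' @param n1_negative Locate N1 as a minimum (default) or maximum.
#' @return A data.frame with columns `component`, `amplitude_uv`,
#'   `latency_ms`, `interval_mean_uv`.
#' @export
#' @examples
#' t <- seq(-100, 600, by = 1)
#' erp <- erp_waveform(-4 * exp(-(t - 100)^2 / 50), fs = 1000, time_ms = t)
#' detect_prominent_points(erp)
detect_prominent_points <- function(erp, windows = default_prominent_windows(),
                                    n1_negative = TRUE) {
  stopifnot(inherits(erp, "erp_waveform"))
  need <- max(vapply(windows, max, numeric(1)))
  if (max(erp$time_ms) < need) {
    stop(sprintf("ERP ends at %g ms but prominent windows need %g ms",
                 max(erp$time_ms), need), call. = FALSE)
  }
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    idx <- which(erp$time_ms >= w[1] & erp$time_ms <= w[2])
    seg <- erp$samples[idx]
    pick <- if (nm == "N1" && n1_negative) which.min(seg) else which.max(seg)
    data.frame(component = nm,
               amplitude_uv = seg[pick],
               latency_ms = erp$time_ms[idx[pick]],
               interval_mean_uv = mean(seg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative EEG band powers of an ERP
#'
#' Raw-periodogram power in each rhythm band, normalized by the total power
#' over the union of bands, so the values sum to one.
#'
#' @param erp An [erp_waveform()] (intended for waveforms already band-limited
#'   to 30 Hz or below).
#' @param bands Named list of `c(lo, hi)` Hz pairs; see [default_bands()].
#'   Bands are half-open `[lo, hi)` so adjacent edges do not double-count.
#' @return Named numeric vector of relative powers summing to 1.
#' @export
relative_band_powers <- function(erp, bands = default_bands()) {
  stopifnot(inherits(erp, "erp_waveform"))
  x <- erp$samples - mean(erp$samples)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * erp$fs / n
  half <- freq > 0 & freq <= erp$fs / 2
  p <- p[half]; freq <- freq[half]
  pw <- vapply(bands, function(b) sum(p[freq >= b[1] & freq < b[2]]),
               numeric(1))
  tot <- sum(pw)
  if (tot <= 0) stop("relative_band_powers: zero power in the band union",
                     call. = FALSE)
  pw / tot
}

#' Prominent-point feature block for one stimulus
#'
#' 16 named features per stimulus: 4 peak amplitudes, 4 peak latencies,
#' 4 interval mean amplitudes and 4 relative band powers. Names encode the
#' stimulus and feature kind, e.g. `s2.N1.amp`, `s2.bp.theta`, and parse back
#' to (stimulus, component/band, kind). Over five stimuli the assembled block
#' therefore counts 80 features.
#'
#' @param erp An [erp_waveform()].
#' @param stimulus Stimulus index used in feature names.
#' @inheritParams detect_prominent_points
#' @inheritParams relative_band_powers
#' @return Named numeric vector of length 16.
#' @export
prominent_block <- function(erp, stimulus = 1,
                            windows = default_prominent_windows(),
                            bands = default_bands()) {
  pp <- detect_prominent_points(erp, windows)
  bp <- relative_band_powers(erp, bands)
  c(stats::setNames(pp$amplitude_uv,
                    sprintf("s%d.%s.amp", stimulus, pp$component)),
    stats::setNames(pp$latency_ms,
                    sprintf("s%d.%s.lat", stimulus, pp$component)),
    stats::setNames(pp$interval_mean_uv,
                    sprintf("s%d.%s.mean", stimulus, pp$component)),
    stats::setNames(as.numeric(bp),
                    sprintf("s%d.bp.%s", stimulus, names(bp))))
}

#' Sliding analysis windows over an ERP
#'
#' Windows of `win_ms` with fractional `overlap` starting at the epoch start;
#' the step is `win_ms * (1 - overlap)` and the last incomplete window is
#' dropped, so the count is `floor((L - win) / step) + 1` for an epoch
#' spanning `L` ms. Windows are half-open in time: `[start, start + win)`.
#'
#' @param erp An [erp_waveform()].
#' @param win_ms Window length, ms.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List of integer sample-index vectors, each with attribute
#'   `start_ms`; the list carries attribute `step_ms`.
#' @export
sliding_windows <- function(erp, win_ms = 25, overlap = 0.5) {
  stopifnot(inherits(erp, "erp_waveform"))
  step <- win_ms * (1 - overlap)
  if (step <= 0) stop("sliding_windows: non-positive step", call. = FALSE)
  t0 <- min(erp$time_ms)
  L <- max(erp$time_ms) - t0
  if (win_ms > L) stop("sliding_windows: window longer than the epoch",
                       call. = FALSE)
  n_win <- floor((L - win_ms) / step + 1e-9) + 1L
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    start <- t0 + (i - 1) * step
    idx <- which(erp$time_ms >= start - 1e-9 &
                   erp$time_ms < start + win_ms - 1e-9)
    attr(idx, "start_ms") <- start
    out[[i]] <- idx
  }
  attr(out, "step_ms") <- step
  out
}

# ---------------------------------------------------------------------------
# 107-entry time-domain characteristic registry.
# Classical signal statistics, correlation properties and entropies computed
# per window. Shared intermediates (moments, diffs, ACF, periodogram) are
# computed once per window; individual catalog entries remain pure functions
# of the window samples.

perm_entropy <- function(x, m) {
  n <- length(x)
  if (n < m + 1) return(0)
  k <- n - m + 1L
  codes <- integer(k)
  for (i in seq_len(k)) {
    codes[i] <- sum(order(x[i:(i + m - 1)]) * m^(seq_len(m) - 1))
  }
  p <- as.numeric(table(codes)) / k
  -sum(p * log(p)) / log(factorial(m))
}

lz76_complexity <- function(b) {
  # LZ76 phrase count of a binary sequence, normalized by n / log2(n)
  n <- length(b)
  if (n < 2) return(0)
  s <- paste(as.integer(b), collapse = "")
  i <- 0L; c_count <- 1L; k <- 1L
  while (i + k < n) {
    sub <- substr(s, i + 1, i + k)
    if (grepl(sub, substr(s, 1, i + k - 1), fixed = TRUE)) {
      k <- k + 1L
    } else {
      c_count <- c_count + 1L
      i <- i + k
      k <- 1L
    }
  }
  c_count / (n / log2(n))
}

safe0 <- function(v) ifelse(is.finite(v), v, 0)

# Chebyshev distance matrix between columns of an m x K template matrix
cheb_dist <- function(tm) {
  D <- abs(outer(tm[1, ], tm[1, ], "-"))
  if (nrow(tm) > 1) {
    for (k in 2:nrow(tm)) D <- pmax(D, abs(outer(tm[k, ], tm[k, ], "-")))
  }
  D
}

# Sample entropy (embedding edim, tolerance r, Chebyshev metric), vectorized
# but numerically identical to pracma::sample_entropy (cross-checked in the
# test suite); the pracma implementation loops in R and is too slow for
# thousands of sliding windows.
fast_sample_entropy <- function(x, edim = 2, r = 0.2 * stats::sd(x)) {
  N <- length(x)
  if (N - edim < 2) return(0)
  K <- N - edim
  datamat <- vapply(seq_len(edim + 1), function(i) x[i:(K + i - 1)],
                    numeric(K))
  datamat <- t(datamat)                 # (edim+1) x K
  correl <- numeric(2)
  for (m in c(edim, edim + 1)) {
    D <- cheb_dist(datamat[seq_len(m), , drop = FALSE])
    i_idx <- row(D); j_idx <- col(D)
    ok <- j_idx > i_idx & i_idx <= N - m - 1
    correl[m - edim + 1] <- sum(D[ok] < r) / (K * K)
  }
  if (correl[2] == 0 || correl[1] == 0) return(0)
  log(correl[1] / correl[2])
}

# Approximate entropy, numerically identical to pracma::approx_entropy
fast_approx_entropy <- function(x, edim = 2, r = 0.2 * stats::sd(x)) {
  N <- length(x)
  res <- numeric(2)
  for (j in 1:2) {
    m <- edim + j - 1
    if (N - m + 1 < 2) return(0)
    K <- N - m + 1
    datamat <- t(vapply(seq_len(m), function(i) x[i:(K + i - 1)], numeric(K)))
    D <- cheb_dist(datamat)
    phi <- rowMeans(D <= r)
    res[j] <- mean(log(phi))
  }
  res[1] - res[2]
}

td_characteristics_all <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("td characteristics need at least 2 samples", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  const <- (s == 0)
  med <- stats::median(x)
  d <- diff(x)
  d2 <- if (n > 2) diff(d) else 0
  q <- stats::quantile(x, c(.05, .1, .25, .75, .9, .95), names = FALSE)
  iqr_v <- q[4] - q[3]
  rng <- max(x) - min(x)
  rmsv <- sqrt(mean(x^2))
  z <- if (const) rep(0, n) else (x - m) / s

  # shared autocorrelation (0 for constant windows)
  lag_max <- min(10L, n - 1L)
  a <- rep(0, 10)
  if (!const) {
    av <- tryCatch(
      as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                            demean = TRUE)$acf)[-1],
      error = function(e) numeric(0))
    av <- safe0(av)
    a[seq_along(av)] <- av
  }
  pa <- rep(0, 5)
  if (!const && n > 2) {
    pv <- tryCatch(
      as.numeric(stats::pacf(x, lag.max = min(5L, n - 2L), plot = FALSE)$acf),
      error = function(e) numeric(0))
    pv <- safe0(pv)
    pa[seq_along(pv)] <- pv
  }
  r1 <- a[1]; r2 <- a[2]
  den <- 1 - r1^2
  ar2_1 <- if (den > 0) r1 * (1 - r2) / den else 0
  ar2_2 <- if (den > 0) (r2 - r1^2) / den else 0

  # shared one-sided periodogram (DC removed)
  pwr <- Mod(stats::fft(x - m))^2
  k_half <- seq(2L, floor(n / 2) + 1L)
  P <- pwr[k_half]
  fn <- (k_half - 1) / n           # cycles/sample, up to 0.5
  Psum <- sum(P)
  if (Psum > 0) {
    pp <- P / Psum
    spec_cent <- sum(fn * pp)
    spec_spread <- sqrt(sum((fn - spec_cent)^2 * pp))
    spec_flat <- exp(mean(log(pp + 1e-300))) / mean(pp)
    spec_low <- sum(pp[fn <= 0.125])
    spec_ent <- if (length(pp) > 1) -sum(pp * log(pp + 1e-300)) / log(length(pp)) else 0
  } else {
    spec_cent <- spec_spread <- spec_flat <- spec_low <- spec_ent <- 0
  }

  hist_ent <- function(k) {
    if (const) return(0)
    cuts <- cut(x, breaks = seq(min(x), max(x), length.out = k + 1),
                include.lowest = TRUE)
    p <- as.numeric(table(cuts)) / n
    p <- p[p > 0]
    -sum(p * log(p)) / log(k)
  }

  r_ent <- 0.2 * s
  sampen <- if (const) 0 else safe0(fast_sample_entropy(x, 2, r_ent))
  apen <- if (const) 0 else safe0(fast_approx_entropy(x, 2, r_ent))

  svd_ent <- 0
  if (!const && n >= 8) {
    M <- stats::embed(x, 4)
    sv <- svd(M, nu = 0, nv = 0)$d^2
    if (sum(sv) > 0) {
      psv <- sv / sum(sv); psv <- psv[psv > 0]
      svd_ent <- -sum(psv * log(psv)) / log(4)
    }
  }

  seg_stat <- function(k, what) {
    if (const || n < 2 * k) return(0)
    len <- floor(n / k)
    vals <- vapply(seq_len(k), function(i) {
      seg <- x[((i - 1) * len + 1):(i * len)]
      if (what == "mean") mean(seg) else stats::sd(seg)
    }, numeric(1))
    stats::sd(vals) / s
  }

  above <- x > m
  runs <- rle(above)
  run_above <- runs$lengths[runs$values]
  interior <- if (n > 2) x[2:(n - 1)] else numeric(0)
  lmax <- if (n > 2) mean(interior > x[1:(n - 2)] & interior > x[3:n]) else 0
  lmin <- if (n > 2) mean(interior < x[1:(n - 2)] & interior < x[3:n]) else 0
  sdd <- stats::sd(d)
  mob <- if (!const && s > 0) sdd / s else 0
  sdd2 <- if (n > 2) stats::sd(d2) else 0
  comp <- if (sdd > 0) (sdd2 / sdd) / mob else 0
  acf_first_zero <- which(a <= 0)[1]; if (is.na(acf_first_zero)) acf_first_zero <- 11
  acf_first_1e <- which(a < exp(-1))[1]; if (is.na(acf_first_1e)) acf_first_1e <- 11
  acf1_diff <- if (!const && length(d) > 2 && stats::sd(d) > 0)
    safe0(tryCatch(as.numeric(stats::acf(d, lag.max = 1, plot = FALSE)$acf)[2],
                   error = function(e) 0)) else 0
  tt <- seq_len(n) - 1
  slope <- sum((tt - mean(tt)) * (x - m)) / sum((tt - mean(tt))^2)
  r2 <- if (const) 0 else safe0(stats::cor(tt, x))^2
  det_sd <- stats::sd(x - slope * tt)

  out <- c(
    # location / scale / moments (23)
    mean = m, median = med, sd = s, mad = stats::mad(x), iqr = iqr_v,
    min = min(x), max = max(x), range = rng, rms = rmsv, energy = mean(x^2),
    skewness = if (const) 0 else mean(z^3),
    kurtosis = if (const) 0 else mean(z^4) - 3,
    trim_mean_10 = mean(x, trim = .1), trim_mean_25 = mean(x, trim = .25),
    mean_abs = mean(abs(x)), mean_abs_dev = mean(abs(x - m)),
    crest = if (rmsv > 0) max(abs(x)) / rmsv else 0,
    q05 = q[1], q10 = q[2], q25 = q[3], q75 = q[4], q90 = q[5], q95 = q[6],
    # proportions / shape (10)
    prop_above_mean = mean(x > m),
    prop_positive = mean(x > 0),
    prop_within_1sd = if (const) 1 else mean(abs(z) < 1),
    prop_within_2sd = if (const) 1 else mean(abs(z) < 2),
    prop_within_3sd = if (const) 1 else mean(abs(z) < 3),
    zero_cross_rate = mean(diff(x >= 0) != 0),
    mean_cross_rate = mean(diff(above) != 0),
    local_max_rate = lmax,
    prop_outlier_2iqr = if (iqr_v > 0)
      mean(x < q[3] - 2 * iqr_v | x > q[4] + 2 * iqr_v) else 0,
    standardized_mean_med = if (const) 0 else (m - med) / s,
    # successive differences (12)
    mean_diff = mean(d), mean_abs_diff = mean(abs(d)), sd_diff = sdd,
    rms_diff = sqrt(mean(d^2)), max_abs_diff = max(abs(d)),
    prop_diff_positive = mean(d > 0),
    hjorth_mobility = mob, hjorth_complexity = comp,
    line_length = sum(abs(d)) / n,
    rms_diff2 = if (n > 2) sqrt(mean(d2^2)) else 0,
    cid_ce = sqrt(sum(d^2)),
    turning_rate = lmax + lmin,
    # autocorrelation structure (20)
    acf_1 = a[1], acf_2 = a[2], acf_3 = a[3], acf_4 = a[4], acf_5 = a[5],
    acf_6 = a[6], acf_7 = a[7], acf_8 = a[8], acf_9 = a[9], acf_10 = a[10],
    pacf_1 = pa[1], pacf_2 = pa[2], pacf_3 = pa[3], pacf_4 = pa[4],
    pacf_5 = pa[5],
    acf_first_zero = acf_first_zero,
    acf_first_1e = acf_first_1e,
    acf_sum_abs_5 = sum(abs(a[1:5])),
    acf_sum_sq_10 = sum(a^2),
    acf1_of_diff = acf1_diff,
    # linear trend / AR structure (8)
    trend_slope = slope, trend_r2 = r2, detrended_sd = det_sd,
    ar1_coef = r1, ar2_coef1 = ar2_1, ar2_coef2 = ar2_2,
    ar1_resid_var_ratio = max(den, 0),
    ar2_resid_var_ratio = max(1 - ar2_1 * r1 - ar2_2 * r2, 0),
    # entropies / complexity (11)
    sample_entropy = sampen, approx_entropy = apen,
    perm_entropy_3 = if (const) 0 else perm_entropy(x, 3),
    perm_entropy_4 = if (const) 0 else perm_entropy(x, 4),
    perm_entropy_5 = if (const) 0 else perm_entropy(x, 5),
    spectral_entropy = spec_ent,
    hist_entropy_5 = hist_ent(5), hist_entropy_10 = hist_ent(10),
    hist_entropy_20 = hist_ent(20),
    lz_complexity = if (const) 0 else lz76_complexity(above),
    svd_entropy = svd_ent,
    # spectral summaries (4)
    spec_centroid = spec_cent, spec_spread = spec_spread,
    spec_flatness = spec_flat, spec_low_frac = spec_low,
    # extremum locations (7)
    pos_max = (which.max(x) - 1) / (n - 1),
    pos_min = (which.min(x) - 1) / (n - 1),
    pos_max_min_dist = abs(which.max(x) - which.min(x)) / (n - 1),
    max_z = if (const) 0 else (max(x) - m) / s,
    min_z = if (const) 0 else (min(x) - m) / s,
    first_last_diff_z = if (const) 0 else (x[n] - x[1]) / s,
    half_mean_diff_z = if (const) 0 else
      (mean(x[1:floor(n / 2)]) - mean(x[(floor(n / 2) + 1):n])) / s,
    # stationarity / runs (12)
    statav_2 = seg_stat(2, "mean"), statav_3 = seg_stat(3, "mean"),
    statav_4 = seg_stat(4, "mean"),
    sdav_2 = seg_stat(2, "sd"), sdav_3 = seg_stat(3, "sd"),
    sdav_4 = seg_stat(4, "sd"),
    longest_run_above_mean = if (length(run_above)) max(run_above) / n else 0,
    run_rate = length(runs$lengths) / n,
    prop_diff_zero = mean(d == 0),
    rms_over_range = if (rng > 0) rmsv / rng else 0,
    mad_over_sd = if (const) 0 else stats::mad(x) / s,
    iqr_over_range = if (rng > 0) iqr_v / rng else 0
  )
  out <- safe0(out)
  out
}

#' The time-domain characteristic catalog
#'
#' An ordered registry of exactly 107 named per-window scalar
#' characteristics: classical signal statistics (moments, order statistics,
#' proportion-within-k-SD), correlation properties (autocorrelations at fixed
#' lags, partial autocorrelations, first ACF zero crossing, linear-trend and
#' AR structure) and entropies (sample, approximate, permutation, spectral,
#' histogram, Lempel-Ziv, SVD), plus spectral and stationarity summaries.
#' Every entry is a pure function of a window's samples; names are stable
#' across runs. Degenerate (constant) windows yield documented fallbacks:
#' scale-normalized quantities fall back to 0, the proportion-within-k-SD
#' family to 1. The exact entry identity is this package's own registry, a
#' declared approximation to large time-series feature libraries.
#'
#' @return An object of class `td_catalog`: list with `names` (length 107),
#'   `fns` (named list of functions) and `version`.
#' @export
#' @examples
#' cat107 <- td_catalog()
#' length(cat107$names)
#' cat107$fns$prop_within_2sd(rnorm(1000))
td_catalog <- function() {
  nms <- names(td_characteristics_all(sin(seq_len(32))))
  fns <- lapply(nms, function(nm) {
    force(nm)
    function(x) unname(td_characteristics_all(x)[nm])
  })
  names(fns) <- nms
  structure(list(names = nms, fns = fns, version = "1.0"),
            class = "td_catalog")
}

#' @export
print.td_catalog <- function(x, ...) {
  cat("time-domain characteristic catalog v", x$version, ": ",
      length(x$names), " entries\n", sep = "")
  invisible(x)
}

#' Compute all time-domain characteristics of one window
#'
#' @param x Numeric window samples (length >= 2).
#' @param catalog A [td_catalog()] (or subset of one).
#' @return Named numeric vector, one finite value per catalog entry.
#' @export
compute_td_characteristics <- function(x, catalog = td_catalog()) {
  td_characteristics_all(x)[catalog$names]
}

#' Slope and coefficient-of-variation dynamics of a characteristic trajectory
#'
#' For each adjacent pair of window values `(f_t, f_{t+1})` computes the
#' slope `(f_{t+1} - f_t) / step_ms` and the pair's coefficient of variation
#' `sd / |mean|`. A pair with zero mean and equal values has CV 0; a pair
#' with zero mean and unequal values has no defined CV and is flagged `NA`
#' (treated as missing downstream).
#'
#' @param vals Per-window values of one characteristic (length >= 2).
#' @param step_ms Window step in ms.
#' @return List with `slopes` and `cvs`, each of length `length(vals) - 1`.
#' @export
slope_cv_dynamics <- function(vals, step_ms) {
  k <- length(vals)
  if (k < 2) stop("slope_cv_dynamics: need at least 2 windows", call. = FALSE)
  slopes <- diff(vals) / step_ms
  cvs <- vapply(seq_len(k - 1), function(i) {
    pair <- vals[c(i, i + 1)]
    mp <- mean(pair); sp <- stats::sd(pair)
    if (mp == 0) {
      if (sp == 0) 0 else NA_real_
    } else {
      sp / abs(mp)
    }
  }, numeric(1))
  list(slopes = slopes, cvs = cvs)
}

#' Screen windowed time-domain features by group separation
#'
#' Automated surrogate for by-eye screening: a feature is retained when its
#' standardized between-group separation, `|mean_1 - mean_2| / pooled SD`,
#' exceeds `cutoff` (or, with `n_keep`, the `n_keep` best-separated features
#' are kept). Deterministic given the data; features with any missing value
#' or zero separation are never retained. Zero pooled SD with distinct group
#' means counts as infinite separation.
#'
#' @param X Numeric matrix, subjects x features, with column names.
#' @param groups Factor/character of group labels (2 levels, >= 2 subjects
#'   each).
#' @param cutoff Separation threshold (ignored when `n_keep` is given).
#' @param n_keep Optionally keep exactly the top `n_keep` features.
#' @return Character vector of retained names, with attribute `separation`
#'   (the full named separation vector).
#' @export
screen_td_features <- function(X, groups, cutoff = 1, n_keep = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2 || min(table(groups)) < 2) {
    stop("screen_td_features: need two groups with >= 2 subjects each",
         call. = FALSE)
  }
  X1 <- X[groups == lev[1], , drop = FALSE]
  X2 <- X[groups == lev[2], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, stats::var); v2 <- apply(X2, 2, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  sep <- abs(m1 - m2) / pooled
  sep[pooled == 0 & m1 != m2] <- Inf
  sep[pooled == 0 & m1 == m2] <- 0
  sep[is.na(sep)] <- 0            # missing-valued features never retained
  if (!is.null(n_keep)) {
    keep <- colnames(X)[order(-sep)[seq_len(min(n_keep, ncol(X)))]]
    keep <- keep[sep[keep] > 0]
  } else {
    keep <- colnames(X)[sep > cutoff]
  }
  attr(keep, "separation") <- sep
  keep
}

#' Windowed time-domain dynamics block for one stimulus ERP
#'
#' Slides 25 ms / 50 %-overlap windows over the ERP, computes the 107-entry
#' characteristic catalog per window, and emits the slope and CV of every
#' characteristic over adjacent window pairs. Names follow
#' `s<stim>.w<pair>.<characteristic>.<slope|cv>`, giving
#' `2 * 107 * (windows - 1)` candidate features per stimulus.
#'
#' @inheritParams prominent_block
#' @inheritParams sliding_windows
#' @param catalog A [td_catalog()].
#' @return Named numeric vector (may contain `NA` for flagged CVs).
#' @export
td_dynamics_block <- function(erp, stimulus = 1, win_ms = 25, overlap = 0.5,
                              catalog = td_catalog()) {
  wins <- sliding_windows(erp, win_ms, overlap)
  step <- attr(wins, "step_ms")
  vals <- vapply(wins, function(idx) compute_td_characteristics(
    erp$samples[idx], catalog), numeric(length(catalog$names)))
  # vals: characteristics x windows
  k <- ncol(vals)
  out <- numeric(0)
  res_s <- matrix(NA_real_, nrow(vals), k - 1)
  res_c <- matrix(NA_real_, nrow(vals), k - 1)
  for (j in seq_len(nrow(vals))) {
    sc <- slope_cv_dynamics(vals[j, ], step)
    res_s[j, ] <- sc$slopes
    res_c[j, ] <- sc$cvs
  }
  nm_s <- as.vector(outer(catalog$names, seq_len(k - 1), function(ch, t)
    sprintf("s%d.w%02d.%s.slope", stimulus, t, ch)))
  nm_c <- as.vector(outer(catalog$names, seq_len(k - 1), function(ch, t)
    sprintf("s%d.w%02d.%s.cv", stimulus, t, ch)))
  c(stats::setNames(as.vector(res_s), nm_s),
    stats::setNames(as.vector(res_c), nm_c))
}

#' Build the candidate feature table (CFV) for a cohort
#'
#' Runs the multi-trial preprocessing chain per subject and stimulus
#' (baseline correction, +/-50 microvolt artifact rejection, grand averaging,
#' 0-30 Hz zero-phase filtering) and assembles the candidate feature vector:
#' the 16-feature prominent block per stimulus plus, optionally, the windowed
#' time-domain dynamics block.
#'
#' @param cohort An `eeg_cohort` (or any list with the same fields).
#' @param td Include the windowed time-domain dynamics block?
#' @param win_ms,overlap Sliding-window settings for the dynamics block.
#' @param threshold_uv Artifact rejection threshold, microvolts.
#' @param band `c(lo, hi)` Hz filter band for the grand average.
#' @param catalog A [td_catalog()].
#' @return List of class `cfv_table`: `X` (subjects x features matrix),
#'   `subjects` (data.frame), `reports` (per subject/stimulus rejection
#'   reports).
#' @export
build_feature_table <- function(cohort, td = TRUE, win_ms = 25, overlap = 0.5,
                                threshold_uv = 50, band = c(0, 30),
                                catalog = td_catalog()) {
  n_sub <- nrow(cohort$subjects)
  rows <- vector("list", n_sub)
  reports <- vector("list", n_sub)
  names(reports) <- cohort$subjects$id
  for (s in seq_len(n_sub)) {
    feats <- numeric(0)
    reports[[s]] <- vector("list", length(cohort$epochs[[s]]))
    for (st in seq_along(cohort$epochs[[s]])) {
      ep <- baseline_correct(cohort$epochs[[s]][[st]])
      rej <- reject_amplitude(ep, threshold_uv)
      reports[[s]][[st]] <- rej$report
      erp <- grand_average(rej$epochs)
      erp <- bandpass_erp(erp, band[1], band[2])
      feats <- c(feats, prominent_block(erp, stimulus = st))
      if (td) {
        feats <- c(feats, td_dynamics_block(erp, stimulus = st,
                                            win_ms = win_ms,
                                            overlap = overlap,
                                            catalog = catalog))
      }
    }
    rows[[s]] <- feats
  }
  X <- do.call(rbind, rows)
  rownames(X) <- cohort$subjects$id
  structure(list(X = X, subjects = cohort$subjects, reports = reports),
            class = "cfv_table")
}

#' @export
print.cfv_table <- function(x, ...) {
  cat(sprintf("candidate feature table: %d subjects x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
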