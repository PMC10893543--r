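test_that("prominent points locate a planted N1 and honor the tie rule", {
  erp <- bump_erp(-4, 100, width_ms = 5)
  pp <- detect_prominent_points(erp)
  n1 <- pp[pp$component == "N1", ]
  expect_equal(n1$amplitude_uv, -4, tolerance = 1e-6)
  expect_equal(n1$latency_ms, 100)
  # window mean oracle
  idx <- erp$time_ms >= 90 & erp$time_ms <= 110
  expect_equal(n1$interval_mean_uv, mean(erp$samples[idx]))

  z <- detect_prominent_points(flat_erp())
  expect_equal(z$amplitude_uv, rep(0, 4))
  expect_equal(z$latency_ms, c(25, 60, 90, 150))   # earliest-latency ties

  short <- erp_waveform(rep(0, 200), fs = 1000, time_ms = seq(-50, 149))
  expect_error(detect_prominent_points(short), "250")
})

test_that("relative band powers normalize to one and localize pure tones", {
  t <- seq(-100, 600) / 1000
  erp6 <- erp_waveform(sin(2 * pi * 6 * t), fs = 1000, time_ms = t * 1000)
  bp <- relative_band_powers(erp6)
  expect_equal(sum(bp), 1, tolerance = 1e-9)
  expect_gte(bp[["theta"]], 0.95)
  expect_error(relative_band_powers(flat_erp(3)), "zero power")
})

test_that("white-noise band powers follow the periodogram bin counts", {
  set.seed(12)
  n <- 701; fs <- 1000
  freq <- (seq_len(n) - 1) * fs / n
  freq <- freq[freq > 0 & freq <= fs / 2]
  bands <- default_bands()
  bins <- vapply(bands, function(b) sum(freq >= b[1] & freq < b[2]),
                 numeric(1))
  acc <- rep(0, 4)
  for (i in 1:30) {
    t <- seq(-100, 600)
    erp <- erp_waveform(rnorm(n), fs = fs, time_ms = t)
    acc <- acc + relative_band_powers(erp)
  }
  # flat spectrum: expected relative power = band bin count / union bins
  expect_equal(unname(acc / 30), unname(bins / sum(bins)), tolerance = 0.1)
})

test_that("one stimulus yields 16 named features, five yield 80, all parseable", {
  erp <- bump_erp(-4, 100)
  blk <- prominent_block(erp, stimulus = 2)
  expect_length(blk, 16)
  expect_false(any(duplicated(names(blk))))
  all5 <- unlist(lapply(1:5, function(s) prominent_block(erp, s)))
  expect_length(all5, 80)
  expect_false(any(duplicated(names(all5))))
  parts <- strsplit(names(all5), ".", fixed = TRUE)
  expect_true(all(lengths(parts) == 3))
  expect_setequal(unique(vapply(parts, `[`, "", 1)), paste0("s", 1:5))
})

test_that("sliding windows follow the floor((L-win)/step)+1 count", {
  expect_length(sliding_windows(flat_erp()), 55)         # 700 ms, 25/12.5 ms
  t <- seq(0, 100)
  erp100 <- erp_waveform(rnorm(101), fs = 1000, time_ms = t)
  expect_length(sliding_windows(erp100, 25, 0), 4)       # disjoint windows
  expect_error(sliding_windows(flat_erp(), 25, 1), "step")
  expect_error(sliding_windows(erp100, 200, 0.5), "longer")
  w <- sliding_windows(flat_erp())
  expect_equal(attr(w, "step_ms"), 12.5)
  expect_equal(attr(w[[1]], "start_ms"), -100)
  expect_true(all(vapply(w, length, 0L) == 25))
})

test_that("the characteristic catalog has 107 stable, unique entries", {
  cat107 <- td_catalog()
  expect_length(cat107$names, 107)
  expect_false(any(duplicated(cat107$names)))
  expect_identical(cat107$names, td_catalog()$names)
  x <- sin(1:40) + cos(3 * (1:40))
  v <- compute_td_characteristics(x)
  expect_length(v, 107)
  expect_true(all(is.finite(v)))
  expect_identical(v, compute_td_characteristics(x))  # deterministic
  # each catalog entry is a pure per-window function agreeing with the batch
  expect_equal(cat107$fns$sd(x), sd(x))
  expect_equal(cat107$fns$acf_1(x),
               unname(acf(x, lag.max = 1, plot = FALSE)$acf[2, 1, 1]))
  expect_error(compute_td_characteristics(3), "2 samples")
})

test_that("proportion within two SD matches the normal value on a large sample", {
  set.seed(5)
  v <- compute_td_characteristics(rnorm(2000))
  expect_equal(v[["prop_within_2sd"]], 2 * pnorm(2) - 1, tolerance = 0.02)
})

test_that("constant windows fall back to documented values, never non-finite", {
  v <- compute_td_characteristics(rep(3, 25))
  expect_true(all(is.finite(v)))
  expect_equal(v[["sd"]], 0)
  expect_equal(v[["prop_within_1sd"]], 1)
  expect_equal(v[["prop_within_2sd"]], 1)
  expect_equal(v[["prop_within_3sd"]], 1)
  expect_equal(v[["skewness"]], 0)
  expect_equal(v[["sample_entropy"]], 0)
  expect_equal(v[["mean"]], 3)
})

test_that("fast entropies agree with the reference implementations", {
  skip_if_not_installed("pracma")
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(25 + i)
    r <- 0.2 * sd(x)
    ref_s <- pracma::sample_entropy(x, edim = 2, r = r, tau = 1)
    if (is.finite(ref_s)) {
      expect_equal(erpmoca:::fast_sample_entropy(x, 2, r), ref_s,
                   tolerance = 1e-12)
    }
    expect_equal(erpmoca:::fast_approx_entropy(x, 2, r),
                 pracma::approx_entropy(x, edim = 2, r = r),
                 tolerance = 1e-12)
  }
})

test_that("slope and CV dynamics follow the pairwise definitions", {
  sc <- slope_cv_dynamics(c(3, 3), 12.5)
  expect_equal(sc$slopes, 0)
  expect_equal(sc$cvs, 0)
  sc2 <- slope_cv_dynamics(c(1, 3), 12.5)
  expect_equal(sc2$slopes, 2 / 12.5)
  expect_equal(sc2$cvs, sd(c(1, 3)) / 2)
  traj <- rnorm(9)
  sc3 <- slope_cv_dynamics(traj, 5)
  expect_length(sc3$slopes, 8)
  expect_length(sc3$cvs, 8)
  # zero-mean unequal pair is flagged missing
  expect_true(is.na(slope_cv_dynamics(c(-1, 1), 1)$cvs))
  expect_error(slope_cv_dynamics(3, 1), "2 windows")
})

test_that("screening retains separated features and matches a brute-force ranking", {
  set.seed(7)
  groups <- rep(c("normal", "mci"), each = 6)
  X <- matrix(rnorm(12 * 30), 12, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  X[, 1] <- 5                                     # identical everywhere
  X[, 2] <- ifelse(groups == "normal", 3, -3) + rnorm(12, 0, 0.1)
  kept <- screen_td_features(X, groups, cutoff = 1)
  expect_false("f1" %in% kept)
  expect_true("f2" %in% kept)
  sep <- attr(kept, "separation")
  # independent loop oracle for the separation ranking
  oracle <- vapply(seq_len(30), function(j) {
    a <- X[groups == "normal", j]; b <- X[groups == "mci", j]
    sp <- sqrt((5 * var(a) + 5 * var(b)) / 10)
    if (sp == 0) if (mean(a) == mean(b)) 0 else Inf
    else abs(mean(a) - mean(b)) / sp
  }, numeric(1))
  expect_equal(order(-sep), order(-oracle))
  expect_equal(unname(sep), oracle)
  topk <- screen_td_features(X, groups, n_keep = 3)
  expect_length(topk, 3)
  expect_equal(topk[1], "f2")
  expect_error(screen_td_features(X[1:3, ], c("a", "a", "b")), "2 subjects")
})

test_that("features are invariant to a constant offset added before baseline", {
  set.seed(8)
  d <- matrix(rnorm(6 * 701), 6, 701)
  row_of <- function(d) {
    erp <- bandpass_erp(grand_average(baseline_correct(tiny_epochs(d))))
    c(prominent_block(erp, 1),
      compute_td_characteristics(erp$samples[100:160]))
  }
  expect_equal(row_of(d), row_of(d + 5), tolerance = 1e-9)
})

test_that("the windowed dynamics block counts 2 x 107 x (windows-1) per stimulus", {
  set.seed(10)
  t <- seq(-50, 150)
  erp <- erp_waveform(rnorm(201), fs = 1000, time_ms = t)
  nw <- length(sliding_windows(erp))
  blk <- td_dynamics_block(erp, stimulus = 4)
  expect_length(blk, 2 * 107 * (nw - 1))
  expect_true(all(grepl("^s4\\.w[0-9]+\\.", names(blk))))
})
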