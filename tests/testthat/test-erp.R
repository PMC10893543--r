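test_that("baseline correction removes the pre-stimulus mean", {
  ep <- tiny_epochs(matrix(7, 3, 701))
  bc <- baseline_correct(ep)
  expect_equal(bc$data, matrix(0, 3, 701))

  set.seed(1)
  ep2 <- tiny_epochs(matrix(rnorm(5 * 701, 2, 4), 5, 701))
  bc2 <- baseline_correct(ep2)
  pre <- which(bc2$time_ms < 0)
  expect_lt(max(abs(rowMeans(bc2$data[, pre]))), 1e-9)
  # the recomputed pre-stimulus mean oracle: original minus its own mean
  expect_equal(bc2$data[2, ],
               ep2$data[2, ] - mean(ep2$data[2, pre]), tolerance = 1e-12)
})

test_that("baseline correction requires a pre-stimulus region", {
  ep <- epoch_set(matrix(1, 2, 601), fs = 1000, t_pre = 0, t_post = 600)
  expect_error(baseline_correct(ep), "pre-stimulus")
})

test_that("a 20 kHz epoch keeps the documented sample-count convention", {
  n <- round((100 + 600) * 20000 / 1000) + 1
  ep <- epoch_set(matrix(0, 1, n), fs = 20000, t_pre = 100, t_post = 600)
  expect_equal(ncol(ep$data), 14001)
  expect_equal(ep$onset_index, 2001)
  expect_equal(ep$time_ms[ep$onset_index], 0)
})

test_that("amplitude rejection is strict beyond the threshold and keeps the boundary", {
  d <- matrix(0, 3, 701)
  d[1, 300] <- 49.9          # kept
  d[2, 300] <- -50.1         # removed
  d[3, 300] <- 50            # exactly at threshold: kept
  r <- reject_amplitude(tiny_epochs(d))
  expect_equal(r$report$kept, c(1L, 3L))
  expect_equal(r$report$n_rejected_amplitude, 1L)
})

test_that("constructed exceedances are counted exactly in a 200-trial set", {
  set.seed(4)
  d <- matrix(rnorm(200 * 701, 0, 5), 200, 701)
  d[abs(d) > 45] <- 0                       # clear accidental exceedances
  bad <- sample(200, 12)
  d[cbind(bad, sample(701, 12, replace = TRUE))] <- 80
  r <- reject_amplitude(tiny_epochs(d))
  expect_equal(length(r$report$kept), 188L)
  expect_equal(r$report$n_input, 200L)
  # idempotence: a second pass removes nothing
  r2 <- reject_amplitude(r$epochs)
  expect_equal(length(r2$report$kept), 188L)
  expect_equal(r2$epochs$data, r$epochs$data)
})

test_that("grand average equals the per-sample loop mean", {
  set.seed(2)
  d <- matrix(rnorm(3 * 701), 3, 701)
  ga <- grand_average(tiny_epochs(d))
  loop <- vapply(seq_len(701), function(j) mean(d[, j]), numeric(1))
  expect_equal(ga$samples, loop, tolerance = 1e-14)
  expect_equal(ga$n_trials_averaged, 3L)

  same <- matrix(rep(sin(seq_len(701) / 20), each = 4), 4, 701)
  expect_equal(grand_average(tiny_epochs(same))$samples, same[1, ])
  expect_error(grand_average(tiny_epochs(matrix(0, 0, 701))), "trials")
})

test_that("averaging 200 trials gains sqrt(200) in noise suppression", {
  set.seed(6)
  noise_sd <- 5
  d <- matrix(rnorm(200 * 701, 0, noise_sd), 200, 701)
  ga <- grand_average(tiny_epochs(d))
  expect_gt(sd(ga$samples), noise_sd / sqrt(200) * 0.85)
  expect_lt(sd(ga$samples), noise_sd / sqrt(200) * 1.15)
})

test_that("grand averaging commutes with baseline correction", {
  set.seed(3)
  ep <- tiny_epochs(matrix(rnorm(6 * 701, 1, 2), 6, 701))
  a <- grand_average(baseline_correct(ep))$samples
  g <- grand_average(ep)
  b <- g$samples - mean(g$samples[g$time_ms < 0])
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the 0-30 Hz filter passes 10 Hz and attenuates 60 Hz by 40 dB", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  tone_amp <- function(x, f) {
    n <- length(x)
    sp <- Mod(fft(x)) / n * 2
    freq <- (seq_len(n) - 1) * fs / n
    max(sp[abs(freq - f) < 0.5])
  }
  mk <- function(f) erp_waveform(sin(2 * pi * f * t), fs = fs,
                                 time_ms = t * 1000)
  lo10 <- bandpass_erp(mk(10))
  expect_gt(tone_amp(lo10$samples, 10), 0.95)
  lo60 <- bandpass_erp(mk(60))
  expect_lt(tone_amp(lo60$samples, 60), 10^(-40 / 20))
  expect_equal(lo10$filter_band, c(0, 30))
  expect_error(bandpass_erp(mk(10), 0, 600), "Nyquist")
  expect_error(bandpass_erp(mk(10), 40, 30), "lo < hi")
})

test_that("single-trial filtering applies the RT and range rules exactly", {
  n <- 20
  d <- matrix(0, n, 701)
  rts <- rep(0.5, n)
  rts[1:7] <- c(0.19, 0.1, 1.51, 2.0, 0.05, 1.6, 0.15)   # 7 RT outliers
  d[7, 300] <- 60; d[7, 301] <- -60                      # overlaps an RT outlier
  d[8, 300] <- 60; d[8, 301] <- -60                      # 3 pure range violators
  d[9, 300] <- 101
  d[10, 350] <- -51; d[10, 351] <- 50
  fl <- filter_single_trials(tiny_epochs(d), rts)
  expect_equal(length(fl$trials), n - 10)
  expect_equal(fl$report$n_rejected_rt, 7L)
  expect_equal(fl$report$n_rejected_amplitude, 3L)
  # kept order preserved
  expect_equal(fl$report$kept, 11:20)
})

test_that("boundary response times and ranges follow the stated bounds", {
  d <- matrix(0, 2, 701)
  d[2, 400] <- 49.5; d[2, 401] <- -49.5    # range 99
  fl <- filter_single_trials(tiny_epochs(d), c(0.19, 1.49))
  expect_equal(fl$report$kept, 2L)
  # truncation: onset to response only, capped at the epoch end
  expect_equal(length(fl$trials[[1]]), 601)
  fl2 <- filter_single_trials(tiny_epochs(d), c(0.3, 0.3))
  expect_equal(length(fl2$trials[[1]]), floor(0.3 * 1000) + 1)
  expect_error(filter_single_trials(tiny_epochs(d), c(0.5)), "response times")
})
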