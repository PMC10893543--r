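test_that("identical spec and seed reproduce the cohort bit for bit", {
  sp <- cohort_spec(n_normal = 3, n_mci = 2, n_stimuli = 2, n_trials = 8,
                    seed = 42)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$epochs[[2]][[1]]$data, b$epochs[[2]][[1]]$data)
  expect_identical(a$rts, b$rts)
  c2 <- generate_cohort(cohort_spec(n_normal = 3, n_mci = 2, n_stimuli = 2,
                                    n_trials = 8, seed = 43))
  expect_false(identical(a$epochs[[1]][[1]]$data, c2$epochs[[1]][[1]]$data))
})

test_that("zero noise and zero artifacts reproduce the template exactly", {
  co <- generate_cohort(noiseless_spec(n_trials = 4, n_stimuli = 2))
  for (s in seq_len(nrow(co$subjects))) {
    for (st in 1:2) {
      tmpl <- co$ground_truth[[s]][[st]]
      for (tr in 1:4) {
        expect_equal(co$epochs[[s]][[st]]$data[tr, ], tmpl, tolerance = 1e-12)
      }
    }
  }
  expect_true(all(co$subjects$moca >= 0 & co$subjects$moca <= 30))
  expect_equal(ncol(co$epochs[[1]][[1]]$data), length(co$time_ms))
})

test_that("group MoCA distributions match their targets over many seeds", {
  means_n <- means_m <- numeric(25)
  for (i in 1:25) {
    co <- generate_cohort(cohort_spec(n_trials = 1, n_stimuli = 1,
                                      noise_sd = 0, seed = 1000 + i))
    means_n[i] <- mean(co$subjects$moca[co$subjects$group == "normal"])
    means_m[i] <- mean(co$subjects$moca[co$subjects$group == "mci"])
  }
  # grand mean of 25 x 15 (resp. 25 x 8) draws: 3 standard errors plus a
  # small allowance for rounding/clipping bias
  expect_lt(abs(mean(means_n) - 27.6), 3 * 1.18 / sqrt(15 * 25) + 0.15)
  expect_lt(abs(mean(means_m) - 23.0), 3 * 1.85 / sqrt(8 * 25) + 0.15)
})

test_that("a planted N1 amplitude slope is recovered by regression on MoCA", {
  co <- generate_cohort(noiseless_spec(
    n_normal = 25, n_mci = 25, n_trials = 1, n_stimuli = 3,
    component_params = n1_only_params(amp_slope = -0.3)))
  # stimulus 3 has unit gain, so the measured peak tracks the slope exactly
  amp <- vapply(seq_len(50), function(s) {
    erp <- grand_average(baseline_correct(co$epochs[[s]][[3]]))
    pp <- detect_prominent_points(erp)
    pp$amplitude_uv[pp$component == "N1"]
  }, numeric(1))
  fit <- stats::lm(amp ~ co$subjects$moca)
  expect_equal(unname(coef(fit)[2]), -0.3, tolerance = 1e-6)
})

test_that("noiseless group N1 separation equals slope times MoCA difference", {
  co <- generate_cohort(noiseless_spec(
    n_normal = 10, n_mci = 10, n_trials = 1, n_stimuli = 3,
    component_params = n1_only_params(amp_slope = -0.3)))
  amp <- vapply(seq_len(20), function(s) {
    min(grand_average(co$epochs[[s]][[3]])$samples)
  }, numeric(1))
  g <- co$subjects$group
  d_amp <- mean(amp[g == "normal"]) - mean(amp[g == "mci"])
  d_moca <- mean(co$subjects$moca[g == "normal"]) -
    mean(co$subjects$moca[g == "mci"])
  expect_equal(d_amp, -0.3 * d_moca, tolerance = 1e-9)
})

test_that("artifact trials exceed the rejection threshold at the set rate", {
  co <- generate_cohort(cohort_spec(
    n_normal = 1, n_mci = 1, n_stimuli = 1, n_trials = 400,
    noise_sd = 0.5, pink_noise_fraction = 0, artifact_rate = 0.1,
    artifact_amplitude = 120, seed = 5))
  n_exceed <- sum(apply(abs(co$epochs[[1]][[1]]$data), 1,
                        max) > 50)
  # binomial 99.7% band around 400 * 0.1
  expect_gt(n_exceed, 40 - 3 * sqrt(400 * 0.1 * 0.9))
  expect_lt(n_exceed, 40 + 3 * sqrt(400 * 0.1 * 0.9))
})

test_that("response times respect the outlier construction", {
  co <- generate_cohort(cohort_spec(n_normal = 2, n_mci = 1, n_stimuli = 1,
                                    n_trials = 300, rt_outlier_rate = 0.1,
                                    seed = 8))
  rt <- unlist(co$rts)
  out <- rt < 0.2 | rt > 1.5
  expect_gt(mean(out), 0.05)
  expect_lt(mean(out), 0.16)
  expect_true(all(rt[out] < 0.2 | rt[out] > 1.5))
})

test_that("invalid specifications fail naming the offending field", {
  expect_error(cohort_spec(artifact_rate = 1.5), "artifact_rate")
  expect_error(cohort_spec(n_trials = 0), "n_trials")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(pink_noise_fraction = 2), "pink_noise_fraction")
  expect_error(cohort_spec(epoch_pre = 0, epoch_post = 0), "epoch_pre")
})

test_that("a cohort round-trips through the plain-text container", {
  co <- generate_cohort(cohort_spec(n_normal = 2, n_mci = 1, n_stimuli = 2,
                                    n_trials = 4, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$subjects$moca, co$subjects$moca)
  expect_equal(back$epochs[[1]][[2]]$data, co$epochs[[1]][[2]]$data,
               tolerance = 1e-10)
  expect_equal(back$rts[[2]][[1]], co$rts[[2]][[1]], tolerance = 1e-10)
})
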