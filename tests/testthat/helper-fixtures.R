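# Shared fixtures, all generated in code.

# component table with only an N1 bump (clean parameter-recovery target)
n1_only_params <- function(amp_slope = -0.3, lat_slope = 0) {
  cp <- default_component_params()
  cp$amp_uv <- c(0, 0, -4, 0)
  cp$amp_slope <- c(0, 0, amp_slope, 0)
  cp$lat_slope <- c(0, 0, lat_slope, 0)
  cp
}

# noiseless cohort for exact template checks
noiseless_spec <- function(n_normal = 3, n_mci = 2, n_stimuli = 1,
                           n_trials = 2, seed = 1, ...) {
  cohort_spec(n_normal = n_normal, n_mci = n_mci, n_stimuli = n_stimuli,
              n_trials = n_trials, noise_sd = 0, artifact_rate = 0,
              rt_outlier_rate = 0, seed = seed, ...)
}

# small epoch_set from an explicit trials x samples matrix (100 ms pre, fs 1 kHz)
tiny_epochs <- function(data, fs = 1000, t_pre = 100, t_post = 600) {
  epoch_set(data, fs = fs, t_pre = t_pre, t_post = t_post,
            subject = "T01", stimulus = 1)
}

# flat ERP waveform covering -100..600 ms
flat_erp <- function(value = 0, fs = 1000) {
  t <- seq(-100, 600, by = 1000 / fs)
  erp_waveform(rep(value, length(t)), fs = fs, time_ms = t)
}

# ERP with a single Gaussian bump
bump_erp <- function(amp, lat_ms, width_ms = 10, fs = 1000) {
  t <- seq(-100, 600, by = 1000 / fs)
  erp_waveform(amp * exp(-((t - lat_ms)^2) / (2 * width_ms^2)),
               fs = fs, time_ms = t)
}

# orthonormal, zero-mean design (columns orthogonal to the intercept) with
# crossprod(X) / n = I, so the lasso solution is the soft-thresholded OLS fit
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n, p + 1))))[, 2:(p + 1)]
  Q * sqrt(n)
}

# scaled-down high-SNR single-trial study: 16 subjects, one stimulus,
# 10 trials each, strong planted N1 amplitude effect, low trial noise
st_study_cohort <- function(seed = 11) {
  cp <- default_component_params()
  cp$amp_slope[cp$component == "N1"] <- -0.5
  generate_cohort(cohort_spec(
    n_normal = 8, n_mci = 8, n_stimuli = 1, n_trials = 10,
    noise_sd = 0.2, component_params = cp,
    artifact_rate = 0, rt_outlier_rate = 0, seed = seed))
}

st_study_cnn_spec <- function(filter_size = 3, dropout = 0.1, epochs = 10) {
  cnn_spec(input_shape = c(12, 12), filter_size = filter_size,
           n_filters = c(4, 4, 4), dense_units = 8,
           dropout = dropout, epochs = epochs, batch_size = 8)
}
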