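#' Default ERP component parameters
#'
#' Morphology and MoCA-sensitivity of the four canonical auditory ERP
#' deflections (Pa, P1, N1, P2) used by the synthetic cohort generator. Each
#' component is a Gaussian bump on the post-stimulus time axis; N1 is negative.
#' Amplitudes and latencies shift linearly with the subject's MoCA score
#' relative to a reference score of 26 points (the normal/MCI boundary):
#' `amp(moca) = amp_uv + amp_slope * (moca - 26)`, and analogously for latency.
#'
#' @return A data.frame with one row per component and columns
#'   `component`, `amp_uv` (baseline peak amplitude, microvolts),
#'   `lat_ms` (baseline peak latency, ms post-stimulus), `width_ms`
#'   (Gaussian standard deviation, ms), `amp_slope` (microvolts per MoCA
#'   point) and `lat_slope` (ms per MoCA point).
#' @export
#' @examples
#' default_component_params()
default_component_params <- function() {
  data.frame(
    component = c("Pa", "P1", "N1", "P2"),
    amp_uv    = c(1.0, 2.0, -4.0, 3.0),
    lat_ms    = c(30, 70, 100, 180),
    width_ms  = c(4, 8, 12, 25),
    amp_slope = c(0.02, 0.05, -0.15, 0.08),
    lat_slope = c(0, -0.2, -0.5, -1.0),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic EEG cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults emulate the study conditions the analysis assumes: 15 cognitively
#' normal subjects (MoCA 27.6 +/- 1.18) and 8 subjects with mild cognitive
#' impairment (MoCA 23.0 +/- 1.85), 5 vowel stimuli with 200 trials each, and
#' 700 ms epochs (100 ms pre-stimulus, 600 ms post-stimulus). The sampling
#' rate defaults to 1000 Hz to keep simulated arrays small; any rate,
#' including 20 kHz acquisition-grade sampling, is supported.
#'
#' @param n_normal,n_mci Number of subjects per group.
#' @param moca_normal_mean,moca_normal_sd,moca_mci_mean,moca_mci_sd Group MoCA
#'   distributions (points); scores are drawn normal, rounded and clipped to
#'   0-30.
#' @param n_stimuli Number of distinct auditory stimuli.
#' @param n_trials Trials per subject per stimulus.
#' @param fs Sampling rate in Hz.
#' @param epoch_pre,epoch_post Pre-/post-stimulus epoch extent in ms.
#' @param component_params ERP component table, see
#'   [default_component_params()].
#' @param noise_sd Trial noise standard deviation in microvolts.
#' @param pink_noise_fraction Fraction (0-1) of noise variance carried by
#'   1/f-shaped (pink) noise; the remainder is white.
#' @param artifact_rate Fraction of trials receiving an artifact deflection.
#' @param artifact_amplitude Peak amplitude of artifact deflections (microvolts).
#' @param rt_logmean,rt_logsd Lognormal response-time parameters (log-seconds).
#' @param rt_outlier_rate Fraction of response times replaced by values
#'   outside the 0.2-1.5 s acceptance band.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_normal = 3, n_mci = 2, n_trials = 10)
#' spec$fs
cohort_spec <- function(n_normal = 15, n_mci = 8,
                        moca_normal_mean = 27.6, moca_normal_sd = 1.18,
                        moca_mci_mean = 23.0, moca_mci_sd = 1.85,
                        n_stimuli = 5, n_trials = 200,
                        fs = 1000, epoch_pre = 100, epoch_post = 600,
                        component_params = default_component_params(),
                        noise_sd = 5, pink_noise_fraction = 0.5,
                        artifact_rate = 0.05, artifact_amplitude = 120,
                        rt_logmean = log(0.55), rt_logsd = 0.25,
                        rt_outlier_rate = 0.03, seed = 1L) {
  spec <- list(
    n_normal = n_normal, n_mci = n_mci,
    moca_normal_mean = moca_normal_mean, moca_normal_sd = moca_normal_sd,
    moca_mci_mean = moca_mci_mean, moca_mci_sd = moca_mci_sd,
    n_stimuli = n_stimuli, n_trials = n_trials,
    fs = fs, epoch_pre = epoch_pre, epoch_post = epoch_post,
    component_params = component_params,
    noise_sd = noise_sd, pink_noise_fraction = pink_noise_fraction,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    rt_logmean = rt_logmean, rt_logsd = rt_logsd,
    rt_outlier_rate = rt_outlier_rate, seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 ||
        v != round(v)) {
      stop("invalid cohort spec: '", field, "' must be a positive integer",
           call. = FALSE)
    }
  }
  for (f in c("n_normal", "n_mci", "n_stimuli", "n_trials")) chk_count(f)
  chk_nonneg <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("invalid cohort spec: '", field, "' must be non-negative",
           call. = FALSE)
    }
  }
  for (f in c("moca_normal_sd", "moca_mci_sd", "noise_sd",
              "artifact_amplitude", "rt_logsd", "epoch_pre", "epoch_post")) {
    chk_nonneg(f)
  }
  chk_frac <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("invalid cohort spec: '", field, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  for (f in c("artifact_rate", "rt_outlier_rate", "pink_noise_fraction")) {
    chk_frac(f)
  }
  if (spec$fs <= 0) stop("invalid cohort spec: 'fs' must be positive Hz",
                         call. = FALSE)
  if (spec$epoch_pre + spec$epoch_post <= 0) {
    stop("invalid cohort spec: 'epoch_pre' + 'epoch_post' must be positive",
         call. = FALSE)
  }
  cp <- spec$component_params
  need <- c("component", "amp_uv", "lat_ms", "width_ms", "amp_slope",
            "lat_slope")
  if (!is.data.frame(cp) || !all(need %in% names(cp))) {
    stop("invalid cohort spec: 'component_params' must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

# 1/f-shaped noise, unit variance, by spectral shaping of white noise.
# Columns of the returned matrix are independent pink-noise traces. The FFT
# runs at the next highly-composite length (epoch sample counts are often
# prime, which makes direct transforms quadratic) and the result is cropped.
pink_noise <- function(n, m) {
  nfft <- stats::nextn(n)
  white <- matrix(stats::rnorm(nfft * m), nfft, m)
  w <- stats::mvfft(white)
  freq <- seq_len(nfft) - 1L
  freq <- pmin(freq, nfft - freq)       # two-sided frequency index
  scale <- 1 / sqrt(pmax(freq, 1))      # 1/f power => 1/sqrt(f) amplitude
  scale[1] <- 0                         # drop DC
  shaped <- Re(stats::mvfft(w * scale, inverse = TRUE))[seq_len(n), ,
                                                        drop = FALSE] / nfft
  sds <- apply(shaped, 2, stats::sd)
  sweep(shaped, 2, pmax(sds, .Machine$double.eps), "/")
}

# Noiseless ERP template for one subject/stimulus on the epoch time axis.
# Stimulus identity scales component amplitudes slightly (vowel continuum
# steps evoke graded responses); moca shifts amplitude/latency linearly.
erp_template <- function(time_ms, moca, stimulus, cp, moca_ref = 26) {
  stim_gain <- 1 + 0.04 * (stimulus - 3)
  y <- numeric(length(time_ms))
  for (i in seq_len(nrow(cp))) {
    amp <- (cp$amp_uv[i] + cp$amp_slope[i] * (moca - moca_ref)) * stim_gain
    lat <- cp$lat_ms[i] + cp$lat_slope[i] * (moca - moca_ref)
    y <- y + amp * exp(-((time_ms - lat)^2) / (2 * cp$width_ms[i]^2))
  }
  y[time_ms < 0] <- 0   # no evoked activity before stimulus onset
  y
}

#' Generate a synthetic EEG cohort
#'
#' Draws MoCA scores per group, builds per-subject noiseless ERP templates
#' whose component amplitudes/latencies depend linearly on MoCA, and
#' superimposes white + pink noise on every trial. A configurable fraction of
#' trials receives an artifact deflection, and per-trial response times are
#' drawn lognormal with a configurable outlier fraction placed outside the
#' 0.2-1.5 s band. The output is fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `eeg_cohort`: a list with `subjects`
#'   (data.frame: id, group, moca), `epochs` (`epochs[[subject]][[stimulus]]`,
#'   an [epoch_set()] of raw trials), `rts` (response times, seconds, same
#'   nesting), `ground_truth` (noiseless templates, same nesting) and `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_normal = 2, n_mci = 2, n_trials = 8,
#'                                   n_stimuli = 2, seed = 7))
#' co$subjects
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  set.seed(spec$seed)

  n_sub <- spec$n_normal + spec$n_mci
  group <- c(rep("normal", spec$n_normal), rep("mci", spec$n_mci))
  moca <- c(
    stats::rnorm(spec$n_normal, spec$moca_normal_mean, spec$moca_normal_sd),
    stats::rnorm(spec$n_mci, spec$moca_mci_mean, spec$moca_mci_sd)
  )
  moca <- pmin(pmax(round(moca), 0), 30)
  subjects <- data.frame(
    id = sprintf("S%02d", seq_len(n_sub)),
    group = group,
    moca = as.integer(moca),
    stringsAsFactors = FALSE
  )

  n_samp <- round((spec$epoch_pre + spec$epoch_post) * spec$fs / 1000) + 1L
  time_ms <- seq(-spec$epoch_pre, spec$epoch_post, by = 1000 / spec$fs)

  epochs <- vector("list", n_sub)
  rts <- vector("list", n_sub)
  truth <- vector("list", n_sub)
  names(epochs) <- names(rts) <- names(truth) <- subjects$id

  for (s in seq_len(n_sub)) {
    epochs[[s]] <- vector("list", spec$n_stimuli)
    rts[[s]] <- vector("list", spec$n_stimuli)
    truth[[s]] <- vector("list", spec$n_stimuli)
    for (st in seq_len(spec$n_stimuli)) {
      tmpl <- erp_template(time_ms, moca[s], st, spec$component_params)
      dat <- matrix(rep(tmpl, each = spec$n_trials), spec$n_trials, n_samp)
      if (spec$noise_sd > 0) {
        w <- matrix(stats::rnorm(spec$n_trials * n_samp), n_samp,
                    spec$n_trials)
        if (spec$pink_noise_fraction > 0) {
          p <- pink_noise(n_samp, spec$n_trials)
          noise <- sqrt(1 - spec$pink_noise_fraction) * w +
            sqrt(spec$pink_noise_fraction) * p
        } else {
          noise <- w
        }
        dat <- dat + spec$noise_sd * t(noise)
      }
      if (spec$artifact_rate > 0) {
        hit <- stats::runif(spec$n_trials) < spec$artifact_rate
        for (tr in which(hit)) {
          center <- stats::runif(1, min(time_ms), max(time_ms))
          sign_a <- sample(c(-1, 1), 1)
          dat[tr, ] <- dat[tr, ] + sign_a * spec$artifact_amplitude *
            exp(-((time_ms - center)^2) / (2 * 50^2))
        }
      }
      epochs[[s]][[st]] <- epoch_set(dat, fs = spec$fs,
                                     t_pre = spec$epoch_pre,
                                     t_post = spec$epoch_post,
                                     subject = subjects$id[s], stimulus = st)
      rt <- stats::rlnorm(spec$n_trials, spec$rt_logmean, spec$rt_logsd)
      rt <- pmin(pmax(rt, 0.21), 1.49)  # bulk inside the acceptance band
      out <- stats::runif(spec$n_trials) < spec$rt_outlier_rate
      n_out <- sum(out)
      if (n_out > 0) {
        low <- stats::runif(n_out) < 0.5
        rt[out] <- ifelse(low, stats::runif(n_out, 0.05, 0.19),
                          stats::runif(n_out, 1.55, 3.0))
      }
      rts[[s]][[st]] <- rt
      truth[[s]][[st]] <- tmpl
    }
  }

  structure(list(subjects = subjects, epochs = epochs, rts = rts,
                 ground_truth = truth, time_ms = time_ms, spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("Synthetic EEG cohort\n")
  cat("  subjects:", nrow(x$subjects),
      sprintf("(%d normal, %d MCI)", sum(x$subjects$group == "normal"),
              sum(x$subjects$group == "mci")), "\n")
  cat("  MoCA range:", paste(range(x$subjects$moca), collapse = "-"), "\n")
  cat("  stimuli:", x$spec$n_stimuli, " trials/stimulus:", x$spec$n_trials,
      "\n")
  cat("  epoch:", -x$spec$epoch_pre, "to", x$spec$epoch_post, "ms at",
      x$spec$fs, "Hz\n")
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Persists a cohort to a directory: `subjects.csv` (id, group, moca),
#' `trials.csv` (subject, stimulus, trial, rt_s), `spec.json`, and one wide
#' CSV of trials x samples per subject/stimulus under `epochs/`.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns an
#'   `eeg_cohort` (without ground-truth templates, which are not persisted).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  tr <- do.call(rbind, lapply(seq_len(nrow(cohort$subjects)), function(s) {
    do.call(rbind, lapply(seq_along(cohort$rts[[s]]), function(st) {
      data.frame(subject = cohort$subjects$id[s], stimulus = st,
                 trial = seq_along(cohort$rts[[s]][[st]]),
                 rt_s = cohort$rts[[s]][[st]])
    }))
  }))
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  sp <- cohort$spec
  sp$component_params <- as.list(sp$component_params)
  jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in seq_len(nrow(cohort$subjects))) {
    for (st in seq_along(cohort$epochs[[s]])) {
      f <- file.path(dir, "epochs",
                     sprintf("%s_stim%d.csv", cohort$subjects$id[s], st))
      utils::write.csv(cohort$epochs[[s]][[st]]$data, f, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  spj <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spj$component_params <- as.data.frame(spj$component_params)
  spec <- do.call(cohort_spec, spj[names(spj) %in% names(formals(cohort_spec))])
  epochs <- vector("list", nrow(subjects))
  rts <- vector("list", nrow(subjects))
  names(epochs) <- names(rts) <- subjects$id
  for (s in seq_len(nrow(subjects))) {
    n_stim <- max(trials$stimulus[trials$subject == subjects$id[s]])
    epochs[[s]] <- vector("list", n_stim)
    rts[[s]] <- vector("list", n_stim)
    for (st in seq_len(n_stim)) {
      f <- file.path(dir, "epochs", sprintf("%s_stim%d.csv", subjects$id[s], st))
      dat <- as.matrix(utils::read.csv(f))
      dimnames(dat) <- NULL
      epochs[[s]][[st]] <- epoch_set(dat, fs = spec$fs, t_pre = spec$epoch_pre,
                                     t_post = spec$epoch_post,
                                     subject = subjects$id[s], stimulus = st)
      rts[[s]][[st]] <- trials$rt_s[trials$subject == subjects$id[s] &
                                      trials$stimulus == st]
    }
  }
  structure(list(subjects = subjects, epochs = epochs, rts = rts,
                 ground_truth = NULL,
                 time_ms = epochs[[1]][[1]]$time_ms, spec = spec),
            class = "eeg_cohort")
}
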