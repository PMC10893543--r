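# bilinear resampling of a matrix onto a fixed grid (for batching TF images)
resize_bilinear <- function(M, out_dims) {
  interp_axis <- function(mat, n_out) {
    n_in <- nrow(mat)
    if (n_in == n_out) return(mat)
    if (n_in == 1) return(mat[rep(1, n_out), , drop = FALSE])
    src <- seq(1, n_in, length.out = n_out)
    lo <- floor(src); hi <- pmin(lo + 1, n_in); w <- src - lo
    mat[lo, , drop = FALSE] * (1 - w) + mat[hi, , drop = FALSE] * w
  }
  M <- interp_axis(M, out_dims[1])
  t(interp_axis(t(M), out_dims[2]))
}

#' Time-frequency image of a single trial
#'
#' Short-time Fourier power of one truncated trial on a 0 to `f_max` Hz
#' frequency axis, log-scaled and resampled to a fixed image shape for
#' batching. Deterministic given the input.
#'
#' @param x Numeric trial samples (microvolts), onset to response.
#' @param fs Sampling rate, Hz.
#' @param f_max Upper frequency bound, Hz (default 100).
#' @param shape `c(rows, cols)` output image size; rows index frequency
#'   (low to high), columns time.
#' @param window_n STFT window length in samples (default `min(64, n/2)`,
#'   Hanning, 75 % overlap).
#' @param normalize One of `"log"` (default), `"log-z"`, `"none"`. The
#'   default keeps absolute log-power: a per-image z-score (`"log-z"`)
#'   removes exactly the between-trial power differences that carry
#'   amplitude effects, so it is available but not the default.
#' @return Object of class `tf_image`: `power` (the image matrix),
#'   `freq_hz`, `time_s` (pre-resampling axes), `normalization`, `label`
#'   (filled by callers).
#' @export
compute_tf_image <- function(x, fs, f_max = 100, shape = c(16, 16),
                             window_n = NULL, normalize = "log") {
  n <- length(x)
  if (is.null(window_n)) window_n <- max(8, min(64, floor(n / 2)))
  if (n < 2 * window_n || n < 16) {
    stop(sprintf("compute_tf_image: trial too short (%d samples) for a %d-sample window",
                 n, window_n), call. = FALSE)
  }
  sg <- signal::specgram(x, n = window_n, Fs = fs,
                         overlap = floor(window_n * 0.75))
  pow <- Mod(sg$S)^2
  keep <- sg$f <= f_max
  pow <- pow[keep, , drop = FALSE]
  freq <- sg$f[keep]
  img <- pow
  if (normalize %in% c("log", "log-z")) img <- log10(img + 1e-12)
  img <- resize_bilinear(img, shape)
  if (normalize == "log-z") {
    s <- stats::sd(img)
    img <- if (s > 0) (img - mean(img)) / s else img - mean(img)
  }
  structure(list(power = img, freq_hz = freq, time_s = sg$t,
                 normalization = normalize, label = NA_real_),
            class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("tf_image: %dx%d (%s), freq 0-%.0f Hz over %.3f s\n",
              nrow(x$power), ncol(x$power), x$normalization,
              max(x$freq_hz), max(x$time_s)))
  invisible(x)
}

#' Single-trial image set for a cohort
#'
#' Applies the single-trial filters (response time in 0.2-1.5 s, trial
#' peak-to-peak range at most 100 microvolts, truncation from onset to
#' response) to every subject/stimulus, then converts each kept trial to a
#' time-frequency image labelled with the subject's MoCA score.
#'
#' @param cohort An `eeg_cohort`.
#' @param shape Image shape passed to [compute_tf_image()].
#' @param f_max Upper frequency bound, Hz.
#' @param rt_min,rt_max,range_max_uv Trial filter settings
#'   (see [filter_single_trials()]).
#' @param baseline Baseline-correct epochs before filtering? (default TRUE)
#' @param normalize Image normalization, see [compute_tf_image()].
#' @return List with `images` (list of matrices), `labels` (MoCA per image),
#'   `subjects` (subject id per image), `manifest` (data.frame: subject,
#'   stimulus, trial, rt, label), `reports`.
#' @export
single_trial_images <- function(cohort, shape = c(16, 16), f_max = 100,
                                rt_min = 0.2, rt_max = 1.5,
                                range_max_uv = 100, baseline = TRUE,
                                normalize = "log") {
  images <- list(); labels <- numeric(); subjects <- character()
  manifest <- list(); reports <- list()
  for (s in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$id[s]
    moca <- cohort$subjects$moca[s]
    for (st in seq_along(cohort$epochs[[s]])) {
      ep <- cohort$epochs[[s]][[st]]
      if (baseline) ep <- baseline_correct(ep)
      fl <- filter_single_trials(ep, cohort$rts[[s]][[st]],
                                 rt_min, rt_max, range_max_uv)
      reports[[paste(sid, st, sep = ".")]] <- fl$report
      for (i in seq_along(fl$trials)) {
        im <- tryCatch(
          compute_tf_image(fl$trials[[i]], ep$fs, f_max, shape,
                           normalize = normalize),
          error = function(e) NULL)
        if (is.null(im)) next   # too-short trial: skipped, counted below
        images[[length(images) + 1L]] <- im$power
        labels <- c(labels, moca)
        subjects <- c(subjects, sid)
        manifest[[length(manifest) + 1L]] <-
          data.frame(subject = sid, stimulus = st,
                     trial = fl$report$kept[i], rt = fl$rts[i],
                     label = moca)
      }
    }
  }
  list(images = images, labels = labels, subjects = subjects,
       manifest = if (length(manifest)) do.call(rbind, manifest) else NULL,
       reports = reports)
}
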