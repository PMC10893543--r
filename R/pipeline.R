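#' Pipeline configuration
#'
#' Assembles a full run configuration with every tunable defaulting to the
#' standard analysis value: +/-50 microvolt artifact threshold, 0-30 Hz ERP
#' band, 25 ms / 50 % sliding windows, 510 screened time-domain features,
#' 5-fold cross-validation throughout, 0.2-1.5 s / 100 microvolt single-trial
#' filters, 0-100 Hz time-frequency images, 5 pre-sample and 15 exploration
#' rounds of Bayesian optimization. The configuration round-trips through
#' JSON losslessly.
#'
#' @param cohort A [cohort_spec()] (or arguments for one as a list).
#' @param seed Top-level seed; every stage derives its randomness from it.
#' @param threshold_uv,band Preprocessing settings.
#' @param td,win_ms,overlap,td_keep Feature settings (`td_keep` = number of
#'   screened windowed features retained alongside the 16-per-stimulus
#'   prominent block).
#' @param k Cross-validation folds.
#' @param methods Regression methods to fit.
#' @param st_shape,st_f_max,st_presample,st_iters,st_filters,st_dense,st_dropout_default,st_epochs_default
#'   Single-trial settings: image shape, frequency bound, BO budget and CNN
#'   architecture defaults.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(cohort = cohort_spec(), seed = 1,
                       threshold_uv = 50, band = c(0, 30),
                       td = TRUE, win_ms = 25, overlap = 0.5, td_keep = 510,
                       k = 5,
                       methods = c("MR_logit", "ER", "SVR", "RR"),
                       st_shape = c(16, 16), st_f_max = 100,
                       st_presample = 5, st_iters = 15,
                       st_filters = c(4, 4, 4), st_dense = 16,
                       st_dropout_default = 0.25, st_epochs_default = 20) {
  if (!inherits(cohort, "cohort_spec")) cohort <- do.call(cohort_spec, cohort)
  structure(list(cohort = cohort, seed = as.integer(seed),
                 threshold_uv = threshold_uv, band = band,
                 td = td, win_ms = win_ms, overlap = overlap,
                 td_keep = td_keep, k = k, methods = methods,
                 st_shape = st_shape, st_f_max = st_f_max,
                 st_presample = st_presample, st_iters = st_iters,
                 st_filters = st_filters, st_dense = st_dense,
                 st_dropout_default = st_dropout_default,
                 st_epochs_default = st_epochs_default),
            class = "run_config")
}

#' Run the multi-trial analysis end to end
#'
#' Simulate (or accept) a cohort, preprocess every subject/stimulus
#' (baseline correction, amplitude rejection, grand average, band-limiting),
#' assemble the candidate feature vector, screen the windowed time-domain
#' block, select features by cross-validated lasso, fit the requested
#' regressors on the selected features, and attach residual diagnostics.
#'
#' @param config A [run_config()].
#' @param cohort Optionally a pre-generated `eeg_cohort` (otherwise
#'   `config$cohort` is simulated).
#' @return Object of class `multitrial_report`: `counts` (per-stage feature
#'   and trial counts), `lasso` (the `moca_lasso` path), `fits` (named list
#'   of `moca_regression`), `diagnostics`, `comparison` (data.frame of
#'   per-method RMSE/MAE), `selected`, `seed`.
#' @export
run_multitrial <- function(config = run_config(), cohort = NULL) {
  if (is.null(cohort)) {
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
  }
  ft <- build_feature_table(cohort, td = config$td, win_ms = config$win_ms,
                            overlap = config$overlap,
                            threshold_uv = config$threshold_uv,
                            band = config$band)
  X <- ft$X
  prom_cols <- grep("\\.w[0-9]+\\.", colnames(X), invert = TRUE)
  n_prom <- length(prom_cols)
  if (config$td && length(prom_cols) < ncol(X)) {
    td_cols <- setdiff(seq_len(ncol(X)), prom_cols)
    kept <- screen_td_features(X[, td_cols, drop = FALSE],
                               ft$subjects$group, n_keep = config$td_keep)
    X <- cbind(X[, prom_cols, drop = FALSE], X[, kept, drop = FALSE])
  }
  y <- ft$subjects$moca
  lp <- cv_lasso(X, y, k = config$k, seed = config$seed)
  sel <- lp$selected
  if (length(sel) == 0) {
    # degenerate null selection: fall back to the first grid point with
    # nonzero support so the regressors have inputs
    nz <- which(lp$n_nonzero > 0)[1]
    sel <- lp$feature_names[lp$beta[, nz] != 0]
  }
  Xs <- X[, sel, drop = FALSE]
  fits <- lapply(config$methods, function(m) {
    moca_regression(Xs, y, method = m, k = config$k, seed = config$seed)
  })
  names(fits) <- config$methods
  diags <- lapply(fits, function(f) {
    tryCatch(check_residuals(f), error = function(e) NULL)
  })
  comparison <- data.frame(
    method = config$methods,
    rmse = vapply(fits, function(f) f$rmse, numeric(1)),
    mae = vapply(fits, function(f) f$mae, numeric(1)),
    row.names = NULL)
  counts <- list(
    n_subjects = nrow(ft$subjects),
    n_stimuli = length(cohort$epochs[[1]]),
    prominent_features = n_prom,
    td_features = ncol(X) - n_prom,
    cfv_features = ncol(X),
    selected_features = length(sel),
    trials_kept = sum(vapply(unlist(ft$reports, recursive = FALSE),
                             function(r) length(r$kept), numeric(1)))
  )
  structure(list(counts = counts, lasso = lp, fits = fits,
                 diagnostics = diags, comparison = comparison,
                 selected = sel, subjects = ft$subjects,
                 seed = config$seed),
            class = "multitrial_report")
}

#' @export
print.multitrial_report <- function(x, ...) {
  cat("multi-trial analysis report (seed", x$seed, ")\n")
  cat(sprintf("  %d subjects, %d stimuli; CFV %d features (%d prominent + %d windowed)\n",
              x$counts$n_subjects, x$counts$n_stimuli,
              x$counts$cfv_features, x$counts$prominent_features,
              x$counts$td_features))
  cat(sprintf("  lasso selected %d features at lambda = %.4g\n",
              x$counts$selected_features, x$lasso$lambda_min))
  cat("  cross-validated scores (MoCA points):\n")
  for (i in seq_len(nrow(x$comparison))) {
    cat(sprintf("    %-8s RMSE %6.3f  MAE %6.3f\n", x$comparison$method[i],
                x$comparison$rmse[i], x$comparison$mae[i]))
  }
  cat(sprintf("  null predictor SD: %.3f\n", stats::sd(x$subjects$moca)))
  invisible(x)
}

#' Run the single-trial analysis end to end
#'
#' Simulate (or accept) a cohort, filter and truncate single trials, build
#' time-frequency images, tune the CNN by GP Bayesian optimization
#' (pre-sample, kernel comparison, EI-guided exploration), and report the
#' final subject-grouped cross-validated RMSE/MAE at the best configuration.
#'
#' @param config A [run_config()].
#' @param cohort Optionally a pre-generated `eeg_cohort`.
#' @param space Hyperparameter grid (default [hyper_space()]).
#' @param bo_k CV folds inside the BO objective (default `config$k`).
#' @return Object of class `singletrial_report`: `bo` (the final
#'   `bo_state`), `final` (a `cnn_cv` at the best configuration), `n_images`,
#'   `reports` (trial-filter reports), `kernel_sse`, `seed`.
#' @export
run_singletrial <- function(config = run_config(), cohort = NULL,
                            space = hyper_space(), bo_k = NULL) {
  if (is.null(cohort)) {
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
  }
  sti <- single_trial_images(cohort, shape = config$st_shape,
                             f_max = config$st_f_max)
  if (length(sti$images) == 0) stop("no trials survived the filters",
                                    call. = FALSE)
  k_obj <- bo_k %||% config$k
  objective <- function(cfg) {
    spec <- cnn_spec(input_shape = config$st_shape,
                     filter_size = cfg$filter_size,
                     n_filters = config$st_filters,
                     dense_units = config$st_dense,
                     dropout = cfg$dropout, epochs = cfg$epochs)
    train_eval_cnn(sti$images, sti$labels, sti$subjects, spec,
                   k = k_obj, seed = config$seed)$rmse
  }
  state <- presample(space, n = config$st_presample, seed = config$seed,
                     objective = objective)
  state <- compare_kernels(state)
  state <- bo_explore(state, n_iter = config$st_iters, objective = objective)
  best <- state$best_config
  final_spec <- cnn_spec(input_shape = config$st_shape,
                         filter_size = best$filter_size,
                         n_filters = config$st_filters,
                         dense_units = config$st_dense,
                         dropout = best$dropout, epochs = best$epochs)
  final <- train_eval_cnn(sti$images, sti$labels, sti$subjects, final_spec,
                          k = k_obj, seed = config$seed)
  structure(list(bo = state, final = final, n_images = length(sti$images),
                 reports = sti$reports, kernel_sse = state$kernel_sse,
                 label_sd = stats::sd(sti$labels),
                 seed = config$seed),
            class = "singletrial_report")
}

#' @export
print.singletrial_report <- function(x, ...) {
  cat("single-trial analysis report (seed", x$seed, ")\n")
  cat(sprintf("  %d trial images; BO evaluated %d configs (kernel: %s)\n",
              x$n_images, length(x$bo$losses), x$bo$kernel_name))
  cat(sprintf("  best config: filter %d, dropout %.2f, epochs %d\n",
              x$bo$best_config$filter_size, x$bo$best_config$dropout,
              x$bo$best_config$epochs))
  cat(sprintf("  final grouped-CV RMSE %.3f, MAE %.3f (label SD %.3f)\n",
              x$final$rmse, x$final$mae, x$label_sd))
  invisible(x)
}
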