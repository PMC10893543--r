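# ---------------------------------------------------------------------------
# Gaussian-process regression with the five comparison kernels.
# Inputs are standardized by the caller; kernels use unit length scales,
# which is the conventional default on z-scored hyperparameter coordinates.

sq_dists <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Gaussian-process kernels
#'
#' Covariance functions used for hyperparameter-response surface modelling:
#' Matern (nu = 5/2), squared-exponential RBF, Rational Quadratic
#' (alpha = 1), Exp-Sine-Squared (periodic, period 1) and Dot Product.
#' All operate on already-standardized coordinates with unit length scale.
#'
#' @param A,B Numeric matrices (rows = points).
#' @param ls Length scale.
#' @param alpha Rational-Quadratic scale mixture parameter.
#' @param period Exp-Sine-Squared period.
#' @param sigma0 Dot-Product inhomogeneity.
#' @return Covariance matrix of dim `nrow(A)` x `nrow(B)`.
#' @name gp_kernels
NULL

#' @rdname gp_kernels
#' @export
kernel_matern <- function(A, B, ls = 1) {
  d <- sqrt(sq_dists(A, B)) / ls
  (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d)
}

#' @rdname gp_kernels
#' @export
kernel_rbf <- function(A, B, ls = 1) exp(-sq_dists(A, B) / (2 * ls^2))

#' @rdname gp_kernels
#' @export
kernel_rational_quadratic <- function(A, B, ls = 1, alpha = 1) {
  (1 + sq_dists(A, B) / (2 * alpha * ls^2))^(-alpha)
}

#' @rdname gp_kernels
#' @export
kernel_expsine <- function(A, B, ls = 1, period = 1) {
  d <- sqrt(sq_dists(A, B))
  exp(-2 * sin(pi * d / period)^2 / ls^2)
}

#' @rdname gp_kernels
#' @export
kernel_dot <- function(A, B, sigma0 = 1) sigma0^2 + tcrossprod(A, B)

bo_kernels <- function() {
  list(Matern = kernel_matern,
       RBF = kernel_rbf,
       RationalQuadratic = kernel_rational_quadratic,
       ExpSineSquared = kernel_expsine,
       DotProduct = kernel_dot)
}

#' Fit / predict a Gaussian-process interpolator
#'
#' Standard GP regression: the posterior mean and standard deviation at new
#' points given noisy observations `(X, y)`, via a Cholesky solve of
#' `K + noise * I`. Used to model the CV-loss surface over hyperparameter
#' configurations.
#'
#' @param X Numeric matrix of training inputs (rows = points).
#' @param y Observed values.
#' @param kernel A kernel function `k(A, B)`; see [gp_kernels].
#' @param noise Observation-noise variance added to the diagonal.
#' @return Object of class `gp_fit`.
#' @export
gp_fit <- function(X, y, kernel = kernel_rational_quadratic, noise = 1e-10) {
  X <- as.matrix(X)
  ym <- mean(y)
  K <- kernel(X, X) + diag(noise, nrow(X))
  Lc <- chol(K + diag(1e-12, nrow(X)))
  alpha <- backsolve(Lc, forwardsolve(t(Lc), y - ym))
  structure(list(X = X, y = y, ym = ym, kernel = kernel, chol = Lc,
                 alpha = alpha, noise = noise), class = "gp_fit")
}

#' @rdname gp_fit
#' @param object A `gp_fit`.
#' @param Xnew Matrix of prediction points.
#' @param ... Unused.
#' @return `predict` returns a list with `mean` and `sd` at `Xnew`.
#' @export
predict.gp_fit <- function(object, Xnew, ...) {
  Xnew <- as.matrix(Xnew)
  Ks <- object$kernel(Xnew, object$X)
  mu <- object$ym + as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(Ks))
  kss <- diag(object$kernel(Xnew, Xnew))
  s2 <- pmax(kss - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(s2))
}

#' Expected Improvement acquisition
#'
#' Scores a candidate by its expected improvement over the best (lowest)
#' observed CV loss under the GP posterior. The default minimization
#' convention is `Z = (f_best - mu) / sigma`,
#' `EI = (f_best - mu) * Phi(Z) + sigma * phi(Z)`, and `EI = 0` when
#' `sigma = 0`, which equals `E[max(f_best - Y, 0)]` for
#' `Y ~ N(mu, sigma^2)`. `mode = "paper"` flips the sign inside `Z` and the
#' linear term (`mu - f_best`), reproducing the printed form of the formula
#' this convention derives from; with argmax selection that form chases high
#' predicted loss, so the minimization form is the default.
#'
#' @param mu Posterior mean(s).
#' @param sigma Posterior standard deviation(s), >= 0.
#' @param f_best Best (lowest) loss observed so far.
#' @param mode `"min"` (default) or `"paper"`.
#' @return EI value(s), vectorized over `mu`/`sigma`.
#' @export
#' @examples
#' expected_improvement(1, 1, 1)    # phi(0) = 0.3989
expected_improvement <- function(mu, sigma, f_best, mode = c("min", "paper")) {
  mode <- match.arg(mode)
  if (any(sigma < 0)) stop("expected_improvement: negative sigma",
                           call. = FALSE)
  imp <- if (mode == "min") f_best - mu else mu - f_best
  z <- ifelse(sigma > 0, imp / sigma, 0)
  ei <- ifelse(sigma > 0,
               imp * stats::pnorm(z) + sigma * stats::dnorm(z),
               0)
  ei
}

#' Discretized CNN hyperparameter space
#'
#' The three tuned hyperparameters on a finite grid, which makes
#' "sampling without repetition" and argmax-EI selection well defined:
#' convolutional filter size (odd, 3-9), dropout rate (0.10-0.60 by 0.05)
#' and training epochs (10-100 by 10).
#'
#' @param filter_size,dropout,epochs Candidate values per dimension.
#' @return data.frame of all configurations (one row each).
#' @export
hyper_space <- function(filter_size = c(3, 5, 7, 9),
                        dropout = seq(0.1, 0.6, by = 0.05),
                        epochs = seq(10, 100, by = 10)) {
  expand.grid(filter_size = filter_size, dropout = dropout, epochs = epochs,
              KEEP.OUT.ATTRS = FALSE)
}

new_bo_state <- function(space) {
  structure(list(space = space, eval_idx = integer(),
                 losses = numeric(), phase = "presample",
                 kernel_name = NULL, kernel = NULL,
                 kernel_sse = NULL, ei_trace = numeric()),
            class = "bo_state")
}

bo_standardize <- function(space) {
  X <- as.matrix(space)
  s <- std_fit(X)
  std_apply(X, s)
}

#' Pre-sample stage of Bayesian optimization
#'
#' Draws `n` distinct configurations uniformly from the space (without
#' repetition), evaluates each with the objective (the CNN's cross-validated
#' RMSE in the intended use), and records the results.
#'
#' @param space Configuration data.frame, e.g. [hyper_space()].
#' @param n Number of pre-sample evaluations (default 5).
#' @param seed Seed for the uniform draw.
#' @param objective Function taking one configuration (a one-row data.frame)
#'   and returning a scalar loss.
#' @return Object of class `bo_state`.
#' @export
presample <- function(space, n = 5, seed = 1, objective) {
  if (nrow(space) < n) {
    stop("presample: space smaller than the number of pre-samples",
         call. = FALSE)
  }
  state <- new_bo_state(space)
  set.seed(seed)
  idx <- sample.int(nrow(space), n)
  for (i in idx) {
    state$eval_idx <- c(state$eval_idx, i)
    state$losses <- c(state$losses, objective(space[i, , drop = FALSE]))
  }
  state
}

#' Kernel comparison stage
#'
#' Fits a GP per candidate kernel to the evaluated (configuration, loss)
#' pairs and scores it by the sum of squared errors of the posterior mean at
#' the training inputs. The minimum-SSE kernel is selected; ties break by
#' the listed kernel order, and a kernel whose fit fails scores infinite SSE
#' rather than aborting.
#'
#' @param state A `bo_state` with at least 2 evaluations.
#' @param kernels Named list of kernel functions (default the five standard
#'   ones: Matern, RBF, RationalQuadratic, ExpSineSquared, DotProduct).
#' @param noise GP diagonal noise.
#' @return The state with `kernel_sse` (named numeric) and the chosen
#'   `kernel`/`kernel_name` set; phase advances to `"explore"`.
#' @export
compare_kernels <- function(state, kernels = bo_kernels(), noise = 1e-10) {
  if (length(state$losses) < 2) {
    stop("compare_kernels: need at least 2 evaluated configurations",
         call. = FALSE)
  }
  Xs <- bo_standardize(state$space)[state$eval_idx, , drop = FALSE]
  sse <- vapply(kernels, function(kf) {
    tryCatch({
      g <- gp_fit(Xs, state$losses, kernel = kf, noise = noise)
      mu <- predict(g, Xs)$mean
      sum((mu - state$losses)^2)
    }, error = function(e) Inf)
  }, numeric(1))
  best <- which(sse == min(sse))[1]
  state$kernel_sse <- sse
  state$kernel_name <- names(kernels)[best]
  state$kernel <- kernels[[best]]
  state$phase <- "explore"
  state
}

#' Exploration stage: EI-guided sequential evaluation
#'
#' Per iteration: fit the GP (chosen kernel) to all evaluated points,
#' compute Expected Improvement over every not-yet-evaluated configuration,
#' evaluate the argmax-EI configuration (ties by first occurrence), and
#' update the best-so-far loss. Stops early (flagged) if the space is
#' exhausted.
#'
#' @param state A `bo_state` after [compare_kernels()] (a kernel must be
#'   chosen).
#' @param n_iter Number of exploration evaluations (default 15).
#' @param objective As in [presample()].
#' @param noise GP diagonal noise.
#' @param ei_mode Passed to [expected_improvement()].
#' @return The state with appended evaluations, `ei_trace`, `best_config`
#'   and `best_loss`; `exhausted` flags an early stop.
#' @export
bo_explore <- function(state, n_iter = 15, objective, noise = 1e-6,
                       ei_mode = "min") {
  if (is.null(state$kernel)) {
    stop("bo_explore: choose a kernel first (compare_kernels)", call. = FALSE)
  }
  Xall <- bo_standardize(state$space)
  state$exhausted <- FALSE
  for (it in seq_len(n_iter)) {
    remaining <- setdiff(seq_len(nrow(state$space)), state$eval_idx)
    if (length(remaining) == 0) {
      state$exhausted <- TRUE
      break
    }
    g <- gp_fit(Xall[state$eval_idx, , drop = FALSE], state$losses,
                kernel = state$kernel, noise = noise)
    p <- predict(g, Xall[remaining, , drop = FALSE])
    ei <- expected_improvement(p$mean, p$sd, min(state$losses),
                               mode = ei_mode)
    pick <- remaining[which.max(ei)]
    state$ei_trace <- c(state$ei_trace, max(ei))
    state$eval_idx <- c(state$eval_idx, pick)
    state$losses <- c(state$losses,
                      objective(state$space[pick, , drop = FALSE]))
  }
  best <- which.min(state$losses)
  state$best_config <- state$space[state$eval_idx[best], , drop = FALSE]
  state$best_loss <- state$losses[best]
  state$phase <- "done"
  state
}

#' @export
print.bo_state <- function(x, ...) {
  cat("Bayesian-optimization state (", x$phase, ")\n", sep = "")
  cat("  evaluated:", length(x$losses), "of", nrow(x$space),
      "configurations\n")
  if (!is.null(x$kernel_name)) {
    cat("  kernel:", x$kernel_name, "\n")
  }
  if (length(x$losses)) {
    cat(sprintf("  best loss so far: %.4f\n", min(x$losses)))
  }
  if (!is.null(x$best_config)) {
    cat("  best config: filter", x$best_config$filter_size,
        "dropout", x$best_config$dropout,
        "epochs", x$best_config$epochs, "\n")
  }
  invisible(x)
}
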