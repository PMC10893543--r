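#' Lasso fit by coordinate descent at one penalty value
#'
#' Minimizes `(1/2N) * sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j |b_j|`
#' by cyclic coordinate descent with soft-thresholding. Columns of `X` are
#' expected standardized (the cross-validated driver [cv_lasso()] handles
#' standardization on training folds); the intercept is profiled out as the
#' mean of the current residual. Convergence is declared when the objective
#' decrease over a full sweep falls below `tol`.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Numeric response.
#' @param lambda Non-negative penalty.
#' @param beta_init Optional warm-start coefficients.
#' @param tol Objective-decrease tolerance (default 1e-7).
#' @param max_iter Sweep cap.
#' @return List with `beta0`, `beta` (named), `objective`, `n_iter`.
#' @export
lasso_fit <- function(X, y, lambda, beta_init = NULL, tol = 1e-7,
                      max_iter = 10000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("lasso_fit: non-finite inputs", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, lambda >= 0)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  xtx_n <- colSums(X^2) / n
  beta0 <- mean(y - X %*% beta)
  r <- y - beta0 - as.numeric(X %*% beta)
  obj <- function() sum(r^2) / (2 * n) + lambda * sum(abs(beta))
  soft <- function(a, l) sign(a) * max(abs(a) - l, 0)
  last <- obj()
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(p)) {
      if (xtx_n[j] == 0) next
      bj_old <- beta[j]
      rho <- sum(X[, j] * r) / n + xtx_n[j] * bj_old
      bj <- soft(rho, lambda) / xtx_n[j]
      if (bj != bj_old) {
        r <- r + X[, j] * (bj_old - bj)
        beta[j] <- bj
      }
    }
    b0_new <- beta0 + mean(r)
    r <- r - (b0_new - beta0)
    beta0 <- b0_new
    cur <- obj()
    if (last - cur < tol || it >= max_iter) break
    last <- cur
  }
  names(beta) <- colnames(X)
  list(beta0 = beta0, beta = beta, objective = obj(), n_iter = it)
}

make_folds <- function(n, k, seed) {
  if (k > n) stop("more folds than observations", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

std_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1          # constant columns pass through centered
  list(mu = mu, sd = sd_)
}

std_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

#' Cross-validated lasso path
#'
#' Fits the lasso along a descending log-spaced lambda grid (from the null
#' threshold `lambda_max = max_j |x_j' y| / N` down to `1e-4 * lambda_max`,
#' 100 values by default) with warm starts, and scores each lambda by k-fold
#' cross-validated mean squared error (the Gaussian deviance).
#' Standardization (per-column z-score) is computed on training folds only.
#' `lambda_min` is the argmin of the CV curve, ties broken toward the larger
#' lambda (the sparser model); the selected features are the nonzero
#' coefficients of the full-data fit at `lambda_min`.
#'
#' @param X Feature matrix with column names.
#' @param y Response (MoCA scores).
#' @param nlambda Grid size.
#' @param lambda Optional explicit grid (descending).
#' @param k Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return Object of class `moca_lasso`: `lambda` (grid), `beta` (features x
#'   lambdas, full-data fits), `beta0`, `cvm` (CV mean squared error),
#'   `n_nonzero`, `lambda_min`, `selected` (names), `folds`.
#' @export
cv_lasso <- function(X, y, nlambda = 100, lambda = NULL, k = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  folds <- make_folds(n, k, seed)
  s_all <- std_fit(X)
  Xs <- std_apply(X, s_all)
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
    lambda <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = nlambda))
  }
  L <- length(lambda)
  p <- ncol(X)

  path_fit <- function(Xm, ym) {
    B <- matrix(0, p, L)
    b0 <- numeric(L)
    warm <- NULL
    for (l in seq_len(L)) {
      f <- lasso_fit(Xm, ym, lambda[l], beta_init = warm)
      B[, l] <- f$beta
      b0[l] <- f$beta0
      warm <- f$beta
    }
    list(B = B, b0 = b0)
  }

  cv_err <- matrix(NA_real_, k, L)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    s_tr <- std_fit(X[tr, , drop = FALSE])
    Xtr <- std_apply(X[tr, , drop = FALSE], s_tr)
    Xte <- std_apply(X[!tr, , drop = FALSE], s_tr)
    pf <- path_fit(Xtr, y[tr])
    pred <- sweep(Xte %*% pf$B, 2, pf$b0, "+")
    cv_err[fold, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(cv_err)
  full <- path_fit(Xs, y)
  nnz <- colSums(full$B != 0)
  best <- which(cvm == min(cvm))[1]       # grid descends: first = largest lambda
  selected <- colnames(X)[full$B[, best] != 0]
  structure(list(lambda = lambda, beta = full$B, beta0 = full$b0,
                 cvm = cvm, n_nonzero = nnz,
                 lambda_min = lambda[best], index_min = best,
                 selected = selected, folds = folds,
                 feature_names = colnames(X), k = k, seed = seed),
            class = "moca_lasso")
}

#' @export
print.moca_lasso <- function(x, ...) {
  cat("cross-validated lasso path\n")
  cat(sprintf("  %d lambdas in [%.3g, %.3g], %d-fold CV\n",
              length(x$lambda), min(x$lambda), max(x$lambda), x$k))
  cat(sprintf("  lambda_min = %.4g (CV MSE %.4g), %d features selected\n",
              x$lambda_min, min(x$cvm), length(x$selected)))
  if (length(x$selected)) {
    cat("  selected:", paste(utils::head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
coef.moca_lasso <- function(object, lambda = object$lambda_min, ...) {
  l <- which.min(abs(object$lambda - lambda))
  stats::setNames(c(object$beta0[l], object$beta[, l]),
                  c("(Intercept)", object$feature_names))
}

#' @export
plot.moca_lasso <- function(x, ...) {
  graphics::plot(log10(x$lambda), x$cvm, type = "b", pch = 20,
                 xlab = "log10(lambda)",
                 ylab = "cross-validated MSE (deviance)", ...)
  graphics::abline(v = log10(x$lambda_min), lty = 2)
  graphics::mtext(sprintf("%d features at lambda_min",
                          length(x$selected)), side = 3, line = 0.2)
  invisible(x)
}

#' Random-forest permutation-importance feature ranking
#'
#' Alternative ranker: permutation importance (%IncMSE) from a random forest
#' regression of the response on all candidate features, in descending order.
#'
#' @param X Feature matrix with column names.
#' @param y Response.
#' @param n_trees Number of trees.
#' @param seed Seed (ranking is deterministic given it).
#' @param top_n Optionally truncate to the best `top_n` features (e.g. 25).
#' @return Character vector of feature names, best first, with attribute
#'   `importance`.
#' @export
rank_features_rf <- function(X, y, n_trees = 500, seed = 1, top_n = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("rank_features_rf: need at least 5 observations",
                        call. = FALSE)
  if (stats::sd(y) == 0) stop("rank_features_rf: constant response",
                              call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  ord <- order(-imp)
  out <- colnames(X)[ord]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  attr(out, "importance") <- imp[ord][seq_along(out)]
  out
}
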