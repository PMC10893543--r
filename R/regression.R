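# Ridge regression with closed-form solve on standardized predictors;
# penalty chosen by inner k-fold CV over a log grid when lambda is NULL.
ridge_train <- function(X, y, lambda = NULL, inner_k = 5, seed = 1,
                        lambda_grid = 10^seq(-4, 3, length.out = 40)) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  solve_ridge <- function(Xm, ym, l) {
    p <- ncol(Xm)
    A <- crossprod(Xm) + diag(l, p)
    b <- crossprod(Xm, ym - mean(ym))
    beta <- solve(A, b)
    list(beta = as.numeric(beta), beta0 = mean(ym))
  }
  if (is.null(lambda)) {
    n <- nrow(X)
    folds <- make_folds(n, min(inner_k, n), seed)
    err <- vapply(lambda_grid, function(l) {
      e <- 0
      for (f in unique(folds)) {
        tr <- folds != f
        st <- std_fit(X[tr, , drop = FALSE])
        fit <- solve_ridge(std_apply(X[tr, , drop = FALSE], st), y[tr], l)
        pred <- fit$beta0 +
          as.numeric(std_apply(X[!tr, , drop = FALSE], st) %*% fit$beta)
        e <- e + sum((y[!tr] - pred)^2)
      }
      e / n
    }, numeric(1))
    lambda <- lambda_grid[which.min(err)]
  }
  fit <- solve_ridge(Xs, y, lambda)
  list(beta = fit$beta, beta0 = fit$beta0, std = s, lambda = lambda)
}

ridge_predict <- function(model, X) {
  model$beta0 + as.numeric(std_apply(X, model$std) %*% model$beta)
}

# logit transform of bounded MoCA with half-point shrinkage at the edges
moca_logit <- function(y, eps = 0.5 / 30) {
  p <- y / 30
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qlogis(p)
}

train_one <- function(X, y, method, hyper, seed) {
  switch(method,
    MR_logit = {
      df <- data.frame(z = moca_logit(y), X)
      list(fit = stats::lm(z ~ ., data = df))
    },
    ER = {
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(X, label = y)
      params <- list(max_depth = hyper$er_depth %||% 3,
                     eta = hyper$er_eta %||% 0.1,
                     objective = "reg:squarederror",
                     nthread = 1, subsample = hyper$er_subsample %||% 1)
      list(fit = xgboost::xgb.train(params = params, data = dm,
                                    nrounds = hyper$er_rounds %||% 100,
                                    verbose = 0))
    },
    SVR = {
      list(fit = e1071::svm(x = X, y = y, type = "eps-regression",
                            kernel = "radial",
                            cost = hyper$svr_cost %||% 1,
                            epsilon = hyper$svr_epsilon %||% 0.1,
                            scale = ncol(X) > 0))
    },
    RR = {
      list(fit = ridge_train(X, y, lambda = hyper$rr_lambda,
                             seed = seed))
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

predict_one <- function(model, method, X) {
  switch(method,
    MR_logit = {
      # small cohorts can leave the linear fit rank-deficient; prediction
      # is still defined (non-estimable directions get dropped)
      z <- suppressWarnings(
        stats::predict(model$fit, newdata = data.frame(X)))
      30 * stats::plogis(as.numeric(z))
    },
    ER = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))),
    SVR = as.numeric(stats::predict(model$fit, X)),
    RR = ridge_predict(model$fit, X)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated MoCA regression
#'
#' Fits one of four regressors of MoCA scores on selected ERP features and
#' scores it by k-fold cross-validated RMSE and MAE on pooled held-out
#' predictions. Fold assignment depends only on `(n, k, seed)`, so the four
#' methods are compared on identical folds.
#'
#' Methods: `MR_logit`, multivariate linear regression of `logit(y/30)`
#' (MoCA is bounded 0-30; edge scores get a half-point shrinkage before the
#' logit) with predictions back-transformed through `30 * logistic(.)`, so
#' predictions always lie in (0, 30); `ER`, ensemble regression by
#' least-squares gradient boosting (100 depth-3 trees, learning rate 0.1, via
#' xgboost); `SVR`, epsilon-insensitive RBF support vector regression
#' (C = 1, epsilon = 0.1, z-scored inputs); `RR`, ridge regression with the
#' penalty chosen by inner 5-fold CV over a log grid.
#'
#' @param X Numeric feature matrix (observations x selected features).
#' @param y MoCA scores (0-30; enforced for `MR_logit`).
#' @param method One of `"MR_logit"`, `"ER"`, `"SVR"`, `"RR"`.
#' @param k Number of CV folds (`k <= length(y)`).
#' @param seed Seed controlling fold assignment and any stochastic learner.
#' @param hyper Named list of hyperparameter overrides (`er_depth`,
#'   `er_eta`, `er_rounds`, `svr_cost`, `svr_epsilon`, `rr_lambda`).
#' @return Object of class `moca_regression` with pooled held-out
#'   `predictions`, `y`, `residuals` (truth minus prediction), `folds`,
#'   `rmse`, `mae`, the `final_model` refit on all data, and bookkeeping.
#' @seealso [score_residuals()], [check_residuals()], [qq_data()]
#' @export
#' @examples
#' set.seed(2)
#' X <- matrix(rnorm(23 * 3), 23, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- round(pmin(pmax(24 + 2 * X[, 1] + rnorm(23), 0), 30))
#' fit <- moca_regression(X, y, method = "RR", k = 5, seed = 1)
#' fit
moca_regression <- function(X, y, method = c("MR_logit", "ER", "SVR", "RR"),
                            k = 5, seed = 1, hyper = list()) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (k > n) stop("moca_regression: more folds than observations",
                  call. = FALSE)
  if (method == "MR_logit" && (any(y < 0) || any(y > 30))) {
    stop("MR_logit requires MoCA scores in [0, 30]", call. = FALSE)
  }
  folds <- make_folds(n, k, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_one(X[tr, , drop = FALSE], y[tr], method, hyper, seed)
    pred[!tr] <- predict_one(model, method, X[!tr, , drop = FALSE])
  }
  res <- y - pred
  sc <- score_residuals(res)
  final <- train_one(X, y, method, hyper, seed)
  structure(list(method = method, predictions = pred, y = y,
                 residuals = res, folds = folds, k = k, seed = seed,
                 rmse = sc[["rmse"]], mae = sc[["mae"]],
                 hyper = hyper, final_model = final,
                 feature_names = colnames(X)),
            class = "moca_regression")
}

#' RMSE and MAE of a residual vector
#'
#' @param residuals Numeric residuals (truth minus prediction), length >= 1.
#' @return Named numeric vector `c(rmse, mae)`.
#' @export
#' @examples
#' score_residuals(c(3, -4))   # sqrt(12.5), 3.5
score_residuals <- function(residuals) {
  if (length(residuals) < 1) {
    stop("score_residuals: empty residual vector", call. = FALSE)
  }
  c(rmse = sqrt(mean(residuals^2)), mae = mean(abs(residuals)))
}

#' @export
print.moca_regression <- function(x, ...) {
  cat(sprintf("MoCA regression (%s), %d-fold CV on %d subjects\n",
              x$method, x$k, length(x$y)))
  cat(sprintf("  held-out RMSE %.3f, MAE %.3f (null-predictor SD %.3f)\n",
              x$rmse, x$mae, stats::sd(x$y)))
  invisible(x)
}

#' @export
summary.moca_regression <- function(object, ...) {
  d <- check_residuals(object)
  cat(sprintf("MoCA regression via %s\n", object$method))
  cat(sprintf("  features: %d (%s%s)\n", length(object$feature_names),
              paste(utils::head(object$feature_names, 5), collapse = ", "),
              if (length(object$feature_names) > 5) ", ..." else ""))
  cat(sprintf("  %d-fold CV: RMSE %.3f points, MAE %.3f points\n",
              object$k, object$rmse, object$mae))
  print(d)
  invisible(d)
}

#' @export
residuals.moca_regression <- function(object, ...) object$residuals

#' @export
fitted.moca_regression <- function(object, ...) object$predictions

#' @export
predict.moca_regression <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$predictions)
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  predict_one(object$final_model, object$method, newdata)
}

#' @export
coef.moca_regression <- function(object, ...) {
  switch(object$method,
    MR_logit = stats::coef(object$final_model$fit),
    RR = stats::setNames(
      c(object$final_model$fit$beta0, object$final_model$fit$beta),
      c("(Intercept)", object$feature_names)),
    stop("coefficients are only defined for MR_logit and RR fits",
         call. = FALSE))
}

#' @export
plot.moca_regression <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  qq <- qq_data(x$residuals)
  graphics::plot(qq$theoretical, qq$sample,
                 xlab = "theoretical normal quantiles",
                 ylab = "sample quantiles (standardized residuals)",
                 main = sprintf("QQ (%s)", x$method), pch = 20)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$predictions, x$residuals,
                 xlab = "fitted MoCA", ylab = "residual (points)",
                 main = "residuals vs fitted", pch = 20)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
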