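# ---------------------------------------------------------------------------
# Compact convolutional network for image -> score regression, implemented in
# base R: three blocks of (2-D convolution, same padding -> relu -> 2x2 max
# pool), then flatten -> dropout -> dense -> tanh -> dense(1), mean-squared
# error loss, adadelta updates. Sized for small time-frequency images; every
# gradient is verified against finite differences in the test suite.

#' Specify the CNN regressor
#'
#' Architecture: exactly three convolution + max-pooling blocks with relu
#' activations, a flatten layer, and two dense layers with a tanh activation
#' in between, ending in a single linear output; compiled with the adadelta
#' optimizer and mean-squared-error loss. The three tunable hyperparameters
#' (convolutional filter size, dropout rate, number of epochs) are the ones
#' searched by Bayesian optimization.
#'
#' @param input_shape `c(H, W)` of the input images.
#' @param filter_size Odd convolution kernel edge (shared by all 3 blocks).
#' @param n_filters Integer vector of 3 filter counts.
#' @param dense_units Hidden dense width.
#' @param dropout Dropout rate applied to the flattened features while
#'   training.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param rho,eps Adadelta decay and stabilizer.
#' @return Object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(16, 16), filter_size = 3,
                     n_filters = c(4, 4, 4), dense_units = 16,
                     dropout = 0.25, epochs = 20, batch_size = 16,
                     rho = 0.95, eps = 1e-6) {
  stopifnot(filter_size %% 2 == 1, length(n_filters) == 3,
            dropout >= 0, dropout < 1, epochs >= 1)
  structure(list(input_shape = input_shape, filter_size = filter_size,
                 n_filters = n_filters, dense_units = dense_units,
                 dropout = dropout, epochs = epochs,
                 batch_size = batch_size, rho = rho, eps = eps),
            class = "cnn_spec")
}

pool_dim <- function(d) floor(d / 2)

cnn_init <- function(spec, seed = 1) {
  set.seed(seed)
  k <- spec$filter_size
  chans <- c(1, spec$n_filters)
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  params <- list()
  for (b in 1:3) {
    fan_in <- k * k * chans[b]
    params[[paste0("W", b)]] <-
      array(stats::rnorm(k * k * chans[b] * chans[b + 1],
                         sd = sqrt(2 / fan_in)),
            dim = c(k, k, chans[b], chans[b + 1]))
    params[[paste0("b", b)]] <- numeric(chans[b + 1])
    H <- pool_dim(H); W <- pool_dim(W)
    if (H < 1 || W < 1) {
      stop("cnn_init: input image too small for three pooling stages",
           call. = FALSE)
    }
  }
  flat <- H * W * chans[4]
  params$Wd1 <- matrix(stats::rnorm(flat * spec$dense_units,
                                    sd = sqrt(1 / flat)),
                       flat, spec$dense_units)
  params$bd1 <- numeric(spec$dense_units)
  params$Wd2 <- matrix(stats::rnorm(spec$dense_units,
                                    sd = sqrt(1 / spec$dense_units)),
                       spec$dense_units, 1)
  params$bd2 <- 0
  params
}

conv_same <- function(X, W, b) {
  # X: H x W x Cin; W: k x k x Cin x Cout
  k <- dim(W)[1]; p <- (k - 1) / 2
  H <- dim(X)[1]; Wd <- dim(X)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  Xp <- array(0, c(H + 2 * p, Wd + 2 * p, cin))
  Xp[p + seq_len(H), p + seq_len(Wd), ] <- X
  out <- array(0, c(H, Wd, cout))
  for (f in seq_len(cout)) {
    acc <- matrix(b[f], H, Wd)
    for (c in seq_len(cin)) {
      for (a in seq_len(k)) {
        for (bb in seq_len(k)) {
          w <- W[a, bb, c, f]
          if (w != 0) {
            acc <- acc + w * Xp[(a - 1) + seq_len(H), (bb - 1) + seq_len(Wd), c]
          }
        }
      }
    }
    out[, , f] <- acc
  }
  out
}

conv_same_backward <- function(X, W, dOut) {
  k <- dim(W)[1]; p <- (k - 1) / 2
  H <- dim(X)[1]; Wd <- dim(X)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  Xp <- array(0, c(H + 2 * p, Wd + 2 * p, cin))
  Xp[p + seq_len(H), p + seq_len(Wd), ] <- X
  dXp <- array(0, dim(Xp))
  dW <- array(0, dim(W))
  db <- numeric(cout)
  for (f in seq_len(cout)) {
    g <- dOut[, , f]
    db[f] <- sum(g)
    for (c in seq_len(cin)) {
      for (a in seq_len(k)) {
        for (bb in seq_len(k)) {
          patch_i <- (a - 1) + seq_len(H); patch_j <- (bb - 1) + seq_len(Wd)
          dW[a, bb, c, f] <- sum(g * Xp[patch_i, patch_j, c])
          dXp[patch_i, patch_j, c] <- dXp[patch_i, patch_j, c] +
            W[a, bb, c, f] * g
        }
      }
    }
  }
  list(dX = dXp[p + seq_len(H), p + seq_len(Wd), , drop = FALSE],
       dW = dW, db = db)
}

maxpool2 <- function(X) {
  H <- dim(X)[1]; W <- dim(X)[2]; C <- dim(X)[3]
  H2 <- pool_dim(H); W2 <- pool_dim(W)
  out <- array(0, c(H2, W2, C))
  amax <- array(0L, c(H2, W2, C))   # linear index into X
  for (c in seq_len(C)) {
    for (i in seq_len(H2)) {
      for (j in seq_len(W2)) {
        ii <- (2 * i - 1):(2 * i); jj <- (2 * j - 1):(2 * j)
        blk <- X[ii, jj, c]
        w <- which.max(blk)
        out[i, j, c] <- blk[w]
        ri <- ii[(w - 1) %% 2 + 1]; rj <- jj[(w - 1) %/% 2 + 1]
        amax[i, j, c] <- ri + (rj - 1) * H + (c - 1) * H * W
      }
    }
  }
  list(out = out, amax = amax)
}

maxpool2_backward <- function(dims, amax, dOut) {
  dX <- array(0, dims)
  dX[as.vector(amax)] <- as.vector(dOut)
  dX
}

cnn_forward <- function(params, x, spec, train = FALSE, dropmask = NULL) {
  cache <- list()
  A <- array(x, c(dim(x)[1], dim(x)[2], 1))
  for (b in 1:3) {
    Z <- conv_same(A, params[[paste0("W", b)]], params[[paste0("b", b)]])
    R <- pmax(Z, 0)
    mp <- maxpool2(R)
    cache[[paste0("A", b)]] <- A
    cache[[paste0("relu_mask", b)]] <- Z > 0
    cache[[paste0("pre_pool_dims", b)]] <- dim(R)
    cache[[paste0("amax", b)]] <- mp$amax
    A <- mp$out
  }
  flat <- as.vector(A)
  cache$flat_dims <- dim(A)
  if (train && spec$dropout > 0) {
    if (is.null(dropmask)) {
      dropmask <- stats::runif(length(flat)) >= spec$dropout
    }
    flat <- flat * dropmask / (1 - spec$dropout)
  }
  cache$dropmask <- dropmask
  cache$flat <- flat
  h_pre <- as.numeric(crossprod(params$Wd1, flat)) + params$bd1
  h <- tanh(h_pre)
  cache$h <- h
  yhat <- sum(params$Wd2 * h) + params$bd2
  list(yhat = yhat, cache = cache)
}

cnn_backward <- function(params, x, spec, fw, dy) {
  cache <- fw$cache
  grads <- list()
  grads$Wd2 <- matrix(dy * cache$h, ncol = 1)
  grads$bd2 <- dy
  dh <- dy * as.numeric(params$Wd2)
  dh_pre <- dh * (1 - cache$h^2)
  grads$Wd1 <- outer(cache$flat, dh_pre)
  grads$bd1 <- dh_pre
  dflat <- as.numeric(params$Wd1 %*% dh_pre)
  if (!is.null(cache$dropmask) && spec$dropout > 0) {
    dflat <- dflat * cache$dropmask / (1 - spec$dropout)
  }
  dA <- array(dflat, cache$flat_dims)
  for (b in 3:1) {
    dR <- maxpool2_backward(cache[[paste0("pre_pool_dims", b)]],
                            cache[[paste0("amax", b)]], dA)
    dZ <- dR * cache[[paste0("relu_mask", b)]]
    cb <- conv_same_backward(cache[[paste0("A", b)]],
                             params[[paste0("W", b)]], dZ)
    grads[[paste0("W", b)]] <- cb$dW
    grads[[paste0("b", b)]] <- cb$db
    dA <- cb$dX
  }
  grads
}

adadelta_step <- function(params, grads, state, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$Eg2[[nm]] <- rho * state$Eg2[[nm]] + (1 - rho) * g^2
    dx <- -sqrt(state$Edx2[[nm]] + eps) / sqrt(state$Eg2[[nm]] + eps) * g
    state$Edx2[[nm]] <- rho * state$Edx2[[nm]] + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + dx
  }
  list(params = params, state = state)
}

#' Train the CNN regressor
#'
#' Minibatch training with adadelta on mean-squared error. Labels are
#' z-scored internally (the inverse transform is stored with the model), so
#' the optimizer sees unit-scale targets regardless of the score range, and
#' input images are standardized by the global training-set mean and SD (a
#' single scalar pair, so between-image differences -- the signal carrier --
#' are preserved; the same transform is applied at prediction time).
#'
#' @param images 3-D array `H x W x N` or list of `H x W` matrices.
#' @param labels Numeric scores, one per image.
#' @param spec A [cnn_spec()].
#' @param seed Seed for weight init, shuffling and dropout.
#' @return Object of class `cnn_model` (parameters, spec, label transform,
#'   per-epoch training loss).
#' @export
train_cnn <- function(images, labels, spec = cnn_spec(), seed = 1) {
  imgs <- as_image_list(images, spec$input_shape)
  n <- length(imgs)
  stopifnot(length(labels) == n, n >= 1)
  x_all <- unlist(imgs)
  x_m <- mean(x_all)
  x_s <- stats::sd(x_all); if (!is.finite(x_s) || x_s == 0) x_s <- 1
  imgs <- lapply(imgs, function(im) (im - x_m) / x_s)
  y_m <- mean(labels)
  y_s <- stats::sd(labels); if (!is.finite(y_s) || y_s == 0) y_s <- 1
  yt <- (labels - y_m) / y_s
  params <- cnn_init(spec, seed)
  zero_like <- lapply(params, function(p) p * 0)
  opt <- list(Eg2 = zero_like, Edx2 = zero_like)
  set.seed(seed + 1)
  epoch_loss <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      gacc <- NULL
      for (i in idx) {
        fw <- cnn_forward(params, imgs[[i]], spec, train = TRUE)
        err <- fw$yhat - yt[i]
        tot <- tot + err^2
        g <- cnn_backward(params, imgs[[i]], spec, fw, 2 * err / length(idx))
        gacc <- if (is.null(gacc)) g else
          mapply(function(a, b) a + b, gacc, g, SIMPLIFY = FALSE)
      }
      upd <- adadelta_step(params, gacc, opt, spec$rho, spec$eps)
      params <- upd$params
      opt <- upd$state
    }
    epoch_loss[ep] <- tot / n
  }
  structure(list(params = params, spec = spec, y_mean = y_m, y_sd = y_s,
                 x_mean = x_m, x_sd = x_s,
                 epoch_loss = epoch_loss, seed = seed),
            class = "cnn_model")
}

as_image_list <- function(images, shape) {
  if (is.list(images)) {
    imgs <- images
  } else if (is.array(images) && length(dim(images)) == 3) {
    imgs <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  } else {
    stop("images must be a list of matrices or an H x W x N array",
         call. = FALSE)
  }
  dims <- vapply(imgs, function(m) dim(m), integer(2))
  if (any(dims[1, ] != shape[1]) || any(dims[2, ] != shape[2])) {
    stop(sprintf("image shape mismatch: expected %dx%d", shape[1], shape[2]),
         call. = FALSE)
  }
  imgs
}

#' @export
predict.cnn_model <- function(object, images, ...) {
  imgs <- as_image_list(images, object$spec$input_shape)
  raw <- vapply(imgs, function(im) {
    im <- (im - object$x_mean) / object$x_sd
    cnn_forward(object$params, im, object$spec, train = FALSE)$yhat
  }, numeric(1))
  raw * object$y_sd + object$y_mean
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: 3 conv/pool blocks (k=%d, filters %s), dense %d, dropout %.2f, %d epochs\n",
    x$spec$filter_size, paste(x$spec$n_filters, collapse = "-"),
    x$spec$dense_units, x$spec$dropout, x$spec$epochs))
  cat(sprintf("  final training MSE (z-scale): %.4f\n",
              utils::tail(x$epoch_loss, 1)))
  invisible(x)
}

#' Subject-grouped cross-validated CNN evaluation
#'
#' k-fold cross-validation with folds grouped by subject: no subject
#' contributes images to both the training and test side of any fold (each
#' single-trial image carries its subject's score, so ungrouped folds would
#' leak labels). Reports pooled held-out RMSE and MAE.
#'
#' @param images As in [train_cnn()].
#' @param labels Numeric score per image.
#' @param subjects Subject identifier per image (grouping key).
#' @param spec A [cnn_spec()].
#' @param k Number of folds (capped at the number of distinct subjects).
#' @param seed Seed (folds, init, dropout).
#' @return Object of class `cnn_cv`: `rmse`, `mae`, pooled `predictions`,
#'   `labels`, `subject_fold` assignment.
#' @export
train_eval_cnn <- function(images, labels, subjects, spec = cnn_spec(),
                           k = 5, seed = 1) {
  imgs <- as_image_list(images, spec$input_shape)
  n <- length(imgs)
  stopifnot(length(labels) == n, length(subjects) == n)
  subj <- unique(subjects)
  if (k > length(subj)) {
    stop("train_eval_cnn: more folds than distinct subjects", call. = FALSE)
  }
  sf <- make_folds(length(subj), k, seed)
  names(sf) <- subj
  fold_of <- sf[as.character(subjects)]
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    model <- train_cnn(imgs[tr], labels[tr], spec, seed = seed + f)
    pred[!tr] <- predict(model, imgs[!tr])
  }
  sc <- score_residuals(labels - pred)
  structure(list(rmse = sc[["rmse"]], mae = sc[["mae"]],
                 predictions = pred, labels = labels,
                 subject_fold = sf, k = k, seed = seed, spec = spec),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat(sprintf("CNN %d-fold subject-grouped CV: RMSE %.3f, MAE %.3f (n = %d)\n",
              x$k, x$rmse, x$mae, length(x$labels)))
  invisible(x)
}
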