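test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("erpmoca")
  spec <- cnn_spec(input_shape = c(8, 8), filter_size = 3,
                   n_filters = c(2, 2, 2), dense_units = 4,
                   dropout = 0, epochs = 1)
  params <- ns$cnn_init(spec, 1)
  set.seed(2)
  x <- matrix(rnorm(64), 8, 8)
  ytar <- 0.7
  loss_fn <- function(p) (ns$cnn_forward(p, x, spec)$yhat - ytar)^2
  fw <- ns$cnn_forward(params, x, spec)
  g <- ns$cnn_backward(params, x, spec, fw, 2 * (fw$yhat - ytar))
  eps <- 1e-6
  set.seed(3)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      num <- (loss_fn(p2) - loss_fn(params)) / eps
      expect_equal(g[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("the network memorizes a degenerate constant-label set", {
  set.seed(4)
  img <- matrix(rnorm(144), 12, 12)
  imgs <- rep(list(img), 20)
  m <- train_cnn(imgs, rep(25, 20),
                 cnn_spec(input_shape = c(12, 12), n_filters = c(2, 2, 2),
                          dense_units = 4, dropout = 0, epochs = 5), seed = 1)
  expect_lt(tail(m$epoch_loss, 1), 1e-3)
  expect_equal(predict(m, imgs[1:3]), rep(25, 3), tolerance = 0.05)
})

test_that("training loss decreases on a small separable problem", {
  set.seed(5)
  imgs <- c(lapply(1:8, function(i) matrix(rnorm(144, 2), 12, 12)),
            lapply(1:8, function(i) matrix(rnorm(144, -2), 12, 12)))
  y <- c(rep(28, 8), rep(21, 8))
  m <- train_cnn(imgs, y, cnn_spec(input_shape = c(12, 12),
                                   n_filters = c(2, 2, 2), dense_units = 4,
                                   dropout = 0, epochs = 8, batch_size = 4),
                 seed = 1)
  expect_lt(tail(m$epoch_loss, 1), m$epoch_loss[1])
  expect_gt(cor(predict(m, imgs), y), 0.9)
})

test_that("training and prediction are deterministic given the seed", {
  set.seed(6)
  imgs <- lapply(1:10, function(i) matrix(rnorm(144), 12, 12))
  y <- rnorm(10, 25, 2)
  spec <- cnn_spec(input_shape = c(12, 12), n_filters = c(2, 2, 2),
                   dense_units = 4, dropout = 0.2, epochs = 3)
  m1 <- train_cnn(imgs, y, spec, seed = 9)
  m2 <- train_cnn(imgs, y, spec, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, imgs), predict(m2, imgs))
})

test_that("architecture and input constraints are enforced", {
  expect_error(cnn_spec(filter_size = 4), "filter_size")
  expect_error(cnn_spec(n_filters = c(2, 2)), "n_filters")
  spec <- cnn_spec(input_shape = c(6, 6), n_filters = c(2, 2, 2))
  expect_error(train_cnn(list(matrix(0, 6, 6)), 1, spec, seed = 1),
               "too small")
  spec12 <- cnn_spec(input_shape = c(12, 12), n_filters = c(2, 2, 2))
  expect_error(train_cnn(list(matrix(0, 8, 8)), 1, spec12, seed = 1),
               "shape mismatch")
})

test_that("cross-validation folds never split a subject", {
  set.seed(7)
  n_sub <- 6
  subjects <- rep(paste0("S", 1:n_sub), each = 5)
  imgs <- lapply(seq_along(subjects), function(i) matrix(rnorm(144), 12, 12))
  y <- rep(rnorm(n_sub, 25, 2), each = 5)
  cv <- train_eval_cnn(imgs, y, subjects,
                       cnn_spec(input_shape = c(12, 12),
                                n_filters = c(2, 2, 2), dense_units = 4,
                                dropout = 0, epochs = 1),
                       k = 3, seed = 1)
  expect_length(cv$subject_fold, n_sub)
  # every image of a subject shares its subject's fold: predictions filled once
  expect_false(any(is.na(cv$predictions)))
  expect_gte(cv$rmse, 0)
  expect_error(train_eval_cnn(imgs, y, subjects, k = 10,
                              spec = cnn_spec(input_shape = c(12, 12))),
               "distinct subjects")
})

test_that("time-frequency images localize a pure tone and are deterministic", {
  fs <- 1000
  x <- sin(2 * pi * 40 * seq(0, 0.6, by = 1 / fs))
  # keep the natural frequency-bin count so rows map linearly onto Hz
  im <- compute_tf_image(x, fs, f_max = 100, shape = c(7, 10))
  expect_s3_class(im, "tf_image")
  bin_hz <- diff(im$freq_hz)[1]
  peak_row <- which.max(rowMeans(im$power))
  row_freq <- seq(min(im$freq_hz), max(im$freq_hz), length.out = 7)[peak_row]
  expect_lte(abs(row_freq - 40), bin_hz)
  im2 <- compute_tf_image(x, fs, f_max = 100, shape = c(7, 10))
  expect_identical(im$power, im2$power)
  expect_true(all(im$freq_hz <= 100))
  expect_error(compute_tf_image(x[1:12], fs), "too short")
})

test_that("bilinear resizing preserves constants and exact sizes", {
  M <- matrix(5, 9, 13)
  r <- erpmoca:::resize_bilinear(M, c(4, 6))
  expect_equal(dim(r), c(4L, 6L))
  expect_true(all(abs(r - 5) < 1e-12))
  A <- matrix(rnorm(36), 6, 6)
  expect_identical(erpmoca:::resize_bilinear(A, c(6, 6)), A)
})

test_that("cohort single-trial images carry subject labels and filters", {
  co <- generate_cohort(cohort_spec(n_normal = 2, n_mci = 2, n_stimuli = 1,
                                    n_trials = 8, noise_sd = 1,
                                    artifact_rate = 0, rt_outlier_rate = 0.3,
                                    seed = 12))
  sti <- single_trial_images(co, shape = c(12, 12))
  expect_equal(length(sti$images), length(sti$labels))
  expect_equal(length(sti$images), nrow(sti$manifest))
  expect_true(all(sti$labels %in% co$subjects$moca))
  expect_lt(length(sti$images), 4 * 8)    # RT outliers were dropped
  rep1 <- sti$reports[[1]]
  expect_equal(rep1$n_input, 8L)
})
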