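test_that("expected improvement matches its closed form and edge cases", {
  expect_equal(expected_improvement(2, 0, 1), 0)          # sigma = 0
  expect_equal(expected_improvement(1, 1, 1), dnorm(0))   # mu at best
  expect_error(expected_improvement(1, -1, 0), "negative sigma")
  # vectorized and non-negative everywhere in the minimization convention
  set.seed(1)
  mu <- rnorm(50); sg <- runif(50); fb <- rnorm(1)
  ei <- expected_improvement(mu, sg, fb)
  expect_length(ei, 50)
  expect_true(all(ei >= 0))
  # EI -> 0 as sigma -> 0 with mu >= f_best
  expect_lt(expected_improvement(fb + 1, 1e-12, fb), 1e-10)
})

test_that("expected improvement matches the Monte-Carlo oracle within 3 SE", {
  set.seed(2)
  n <- 2e5
  for (sg in c(0.5, 1, 2)) {
    mu <- rnorm(1); fb <- rnorm(1)
    draws <- pmax(fb - rnorm(n, mu, sg), 0)
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(expected_improvement(mu, sg, fb) - mean(draws)), 3 * se)
  }
})

test_that("the paper-literal mode reproduces the printed sign convention", {
  mu <- 1.7; sg <- 0.8; fb <- 1.2
  z <- (mu - fb) / sg
  expect_equal(expected_improvement(mu, sg, fb, mode = "paper"),
               (mu - fb) * pnorm(z) + sg * dnorm(z))
  expect_equal(expected_improvement(mu, sg, fb, mode = "min"),
               (fb - mu) * pnorm((fb - mu) / sg) + sg * dnorm((fb - mu) / sg))
})

test_that("presampling draws distinct seeded configurations", {
  space <- hyper_space()
  obj <- function(cfg) cfg$dropout
  a <- presample(space, 5, seed = 3, objective = obj)
  b <- presample(space, 5, seed = 3, objective = obj)
  expect_identical(a$eval_idx, b$eval_idx)
  expect_length(a$eval_idx, 5)
  expect_false(any(duplicated(a$eval_idx)))
  expect_error(presample(space[1:3, ], 5, seed = 1, objective = obj),
               "smaller")
})

test_that("smooth kernels interpolate noiseless observations", {
  X <- matrix(seq(-2, 2, by = 0.8))
  y <- sin(2 * X[, 1])
  for (nm in c("Matern", "RBF", "RationalQuadratic")) {
    g <- gp_fit(X, y, erpmoca:::bo_kernels()[[nm]], noise = 0)
    sse <- sum((predict(g, X)$mean - y)^2)
    expect_lt(sse, 1e-10)
  }
  # posterior SD vanishes at training points and grows away from them
  g <- gp_fit(X, y, kernel_matern, noise = 0)
  p <- predict(g, rbind(X, 10))
  expect_lt(max(p$sd[1:6]), 1e-5)
  expect_gt(p$sd[7], 0.5)
})

test_that("kernel comparison picks an interpolating kernel over a misfit", {
  space <- data.frame(filter_size = seq(3, 9, length.out = 8),
                      dropout = seq(0.1, 0.45, length.out = 8),
                      epochs = seq(10, 80, length.out = 8))
  # oscillatory loss surface: a linear (DotProduct) GP cannot fit it
  obj <- function(cfg) sin(20 * cfg$dropout)
  st <- presample(space, 6, seed = 4, objective = obj)
  st <- compare_kernels(st)
  expect_named(st$kernel_sse, c("Matern", "RBF", "RationalQuadratic",
                                "ExpSineSquared", "DotProduct"))
  expect_false(st$kernel_name == "DotProduct")
  expect_gt(st$kernel_sse[["DotProduct"]], min(st$kernel_sse) + 1e-6)
  expect_equal(st$kernel_name, names(which.min(st$kernel_sse)))
  expect_error(compare_kernels(erpmoca:::new_bo_state(space)), "2 evaluated")
})

test_that("EI exploration finds a quadratic optimum within one grid step", {
  space <- hyper_space()
  obj <- function(cfg) (cfg$dropout - 0.35)^2
  hits <- 0
  for (s in 1:10) {
    st <- presample(space, 5, seed = s, objective = obj)
    st <- compare_kernels(st)
    st <- bo_explore(st, 15, objective = obj)
    hits <- hits + (abs(st$best_config$dropout - 0.35) <= 0.05)
  }
  expect_gte(hits, 9)
})

test_that("exploration bookkeeping is monotone, duplicate-free, and sized", {
  space <- hyper_space()
  obj <- function(cfg) cfg$dropout + cfg$filter_size / 100
  st <- presample(space, 5, seed = 6, objective = obj)
  st <- compare_kernels(st)
  st <- bo_explore(st, 15, objective = obj)
  expect_length(st$losses, 5 + 15)
  expect_false(any(duplicated(st$eval_idx)))
  expect_equal(st$best_loss, min(st$losses))
  expect_false(st$exhausted)
  # cumulative best never increases over the evaluation order
  expect_true(all(diff(cummin(st$losses)) <= 0))
  expect_error(bo_explore(presample(space, 3, seed = 1, objective = obj),
                          2, objective = obj), "kernel")
})

test_that("an exhausted space stops early with the flag set", {
  space <- hyper_space(filter_size = 3, dropout = c(0.1, 0.2),
                       epochs = c(10, 20, 30))   # 6 configurations
  obj <- function(cfg) cfg$dropout * cfg$epochs
  st <- presample(space, 5, seed = 7, objective = obj)
  st <- compare_kernels(st)
  st <- bo_explore(st, 10, objective = obj)
  expect_true(st$exhausted)
  expect_length(st$losses, 6)
})
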