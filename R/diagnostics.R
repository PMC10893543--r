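#' Normal QQ coordinates of residuals
#'
#' Standardizes the residuals, sorts them, and pairs the i-th order statistic
#' with the normal quantile at plotting position `(i - 0.5) / n`. The sample
#' coordinate is location-scale equivariant; with the default
#' standardization a normal sample should fall near the identity line.
#'
#' @param residuals Numeric vector, length >= 3.
#' @param standardize Standardize the sample coordinate? (default TRUE)
#' @return data.frame with columns `theoretical` and `sample`, sorted
#'   ascending.
#' @export
#' @examples
#' qq_data(rnorm(9))$theoretical[5]   # median position -> 0
qq_data <- function(residuals, standardize = TRUE) {
  n <- length(residuals)
  if (n < 3) stop("qq_data: need at least 3 residuals", call. = FALSE)
  r <- residuals
  if (standardize) {
    s <- stats::sd(r)
    if (s == 0) stop("qq_data: constant residuals", call. = FALSE)
    r <- (r - mean(r)) / s
  }
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(r))
}

# runs test of residual-sign randomness in fitted order (normal approximation)
runs_test <- function(signs) {
  signs <- signs[signs != 0]
  n1 <- sum(signs > 0); n2 <- sum(signs < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(list(statistic = 0, p_value = 1))
  runs <- 1 + sum(diff(signs) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Residual diagnostics for a cross-validated regression
#'
#' Automated surrogate for by-eye residual inspection, reported as
#' statistics with decisions (never bare booleans): normality by
#' Shapiro-Wilk on the held-out residuals; structure over the fitted values
#' by (a) the correlation of |residual| with fitted value (a
#' heteroscedasticity signal) and (b) a runs test of residual signs ordered
#' by fitted value (a trend/clumping signal); the two structure signals are
#' combined with a Bonferroni split (each at `alpha / 2`) so the pattern
#' decision keeps an approximate level-`alpha` false-alarm rate.
#'
#' @param x A `moca_regression` fit, or a numeric residual vector.
#' @param fitted Fitted values (required when `x` is a plain vector).
#' @param alpha Decision level.
#' @return Object of class `residual_diagnostics`: `qq` (from [qq_data()]),
#'   `shapiro_w`, `shapiro_p`, `normality_ok`, `abs_cor`, `abs_cor_p`,
#'   `runs_z`, `runs_p`, `pattern_ok`, `alpha`, `n`.
#' @export
check_residuals <- function(x, fitted = NULL, alpha = 0.05) {
  if (inherits(x, "moca_regression")) {
    res <- x$residuals
    fitted <- x$predictions
  } else {
    res <- as.numeric(x)
    if (is.null(fitted)) stop("check_residuals: 'fitted' required",
                              call. = FALSE)
  }
  n <- length(res)
  if (n < 8) stop("check_residuals: need at least 8 residuals for decisions",
                  call. = FALSE)
  if (stats::sd(res) == 0) {
    stop("check_residuals: constant residuals, normality undefined",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(res)
  ct <- suppressWarnings(stats::cor.test(abs(res), fitted))
  abs_cor <- unname(ct$estimate)
  abs_p <- ct$p.value
  if (is.na(abs_cor)) { abs_cor <- 0; abs_p <- 1 }   # constant fitted values
  rt <- runs_test(sign(res[order(fitted)]))
  structure(list(
    qq = qq_data(res),
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    normality_ok = sw$p.value >= alpha,
    abs_cor = abs_cor, abs_cor_p = abs_p,
    runs_z = rt$statistic, runs_p = rt$p_value,
    pattern_ok = abs_p >= alpha / 2 && rt$p_value >= alpha / 2,
    alpha = alpha, n = n
  ), class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat("residual diagnostics (n =", x$n, ")\n")
  cat(sprintf("  normality: Shapiro-Wilk W = %.3f, p = %.3g -> %s at alpha = %g\n",
              x$shapiro_w, x$shapiro_p,
              if (x$normality_ok) "consistent with normal" else "rejected",
              x$alpha))
  cat(sprintf("  |residual|~fitted: r = %.3f (p = %.3g); sign runs: z = %.2f (p = %.3g) -> %s\n",
              x$abs_cor, x$abs_cor_p, x$runs_z, x$runs_p,
              if (x$pattern_ok) "no structure detected" else
                "structure detected"))
  invisible(x)
}

#' @export
plot.residual_diagnostics <- function(x, ...) {
  graphics::plot(x$qq$theoretical, x$qq$sample, pch = 20,
                 xlab = "theoretical normal quantiles",
                 ylab = "sample quantiles", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
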