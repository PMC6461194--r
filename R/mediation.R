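#' Covariate-adjusted three-variable mediation with bootstrap inference
#'
#' Standardizes x, m and y, then fits three OLS regressions sharing one
#' covariate set: `m ~ x + C` (path a), `y ~ x + m + C` (paths c' and b),
#' and `y ~ x + C` (total effect c). Because the covariate set is identical
#' across equations, the decomposition `c = c' + a*b` holds exactly. The
#' indirect effect `a*b` gets a nonparametric percentile bootstrap
#' confidence interval (subjects resampled with replacement, seeded);
#' a Sobel z-test is reported as a secondary, normal-theory check.
#'
#' @param x,m,y per-subject exposure, mediator and outcome (equal length).
#' @param covariates optional data.frame entering all three regressions.
#' @param n_boot bootstrap resamples for the indirect-effect CI
#'   (default 5000; use >= 1000 for stable intervals).
#' @param seed integer seed for the bootstrap resampling.
#' @param conf confidence level of the percentile interval.
#' @return an object of class `mediation_result`: paths `a`, `b`, `c`,
#'   `c_prime` with p-values, `indirect` (= a*b), `ci_indirect`,
#'   `sobel_z`/`sobel_p`, `n_boot`, `seed`.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL,
                          n_boot = 5000, seed = 1L, conf = 0.95) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n_boot >= 1)
  for (nm in c("x", "m", "y")) {
    v <- get(nm)
    if (!all(is.finite(v))) stop(nm, " contains non-finite values")
    if (stats::sd(v) == 0) stop(nm, " is constant")
  }
  ncov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= ncov + 3) stop("too few subjects for mediation with this covariate set")

  xs <- as.numeric(scale(x)); ms <- as.numeric(scale(m)); ys <- as.numeric(scale(y))
  C <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE]

  Xa <- cbind("(Intercept)" = 1, x = xs, C)
  Xb <- cbind("(Intercept)" = 1, x = xs, m = ms, C)
  check_full_rank(Xb)

  fa <- ols_coef_test(Xa, ms)    # m ~ x + C
  fb <- ols_coef_test(Xb, ys)    # y ~ x + m + C
  fc <- ols_coef_test(Xa, ys)    # y ~ x + C

  a <- fa$coef["x"]; b <- fb$coef["m"]
  c_prime <- fb$coef["x"]; c_total <- fc$coef["x"]

  set.seed(seed)
  boots <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ab <- stats::lm.fit(Xa[idx, , drop = FALSE], ms[idx])$coefficients
    bb <- stats::lm.fit(Xb[idx, , drop = FALSE], ys[idx])$coefficients
    boots[i] <- ab[["x"]] * bb[["m"]]
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))

  sobel_se <- sqrt(b^2 * fa$se["x"]^2 + a^2 * fb$se["m"]^2)
  sobel_z <- unname(a * b / sobel_se)

  structure(list(a = unname(a), b = unname(b),
                 c = unname(c_total), c_prime = unname(c_prime),
                 indirect = unname(a * b), ci_indirect = ci,
                 p_a = unname(fa$p["x"]), p_b = unname(fb$p["m"]),
                 p_c = unname(fc$p["x"]), p_c_prime = unname(fb$p["x"]),
                 sobel_z = sobel_z,
                 sobel_p = 2 * stats::pnorm(abs(sobel_z), lower.tail = FALSE),
                 significant_indirect = ci[1] > 0 || ci[2] < 0,
                 conf = conf, n = n, n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

## internal: OLS with coefficient-wise t-tests on a prebuilt design matrix
ols_coef_test <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  df_res <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(qr.R(fit$qr))
  piv <- fit$qr$pivot
  coefs <- stats::setNames(fit$coefficients, colnames(X)[piv])
  se <- stats::setNames(sqrt(sigma2 * diag(XtXinv)), colnames(X)[piv])
  tv <- coefs / se
  p <- 2 * stats::pt(abs(tv), df_res, lower.tail = FALSE)
  list(coef = coefs, se = se, t = tv, p = p, df = df_res)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation (standardized paths):\n")
  cat(sprintf("  a  = %7.4f (p = %.4g)   X -> M\n", x$a, x$p_a))
  cat(sprintf("  b  = %7.4f (p = %.4g)   M -> Y | X\n", x$b, x$p_b))
  cat(sprintf("  c  = %7.4f (p = %.4g)   total X -> Y\n", x$c, x$p_c))
  cat(sprintf("  c' = %7.4f (p = %.4g)   direct X -> Y | M\n", x$c_prime, x$p_c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% bootstrap CI [%.4f, %.4f] (%d resamples)%s\n",
              x$indirect, round(100 * x$conf), x$ci_indirect[1], x$ci_indirect[2],
              x$n_boot, if (x$significant_indirect) " *" else ""))
  cat(sprintf("  Sobel z = %.3f (p = %.4g)\n", x$sobel_z, x$sobel_p))
  invisible(x)
}
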