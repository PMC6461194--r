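#' Composite cognitive domain z-scores
#'
#' Standardizes each raw test against the whole analyzed sample
#' (mean/SD over all subjects), flips the sign of lower-is-better
#' (typically timed) tests after standardization so that higher always
#' means better, and averages the member z-scores within each domain.
#'
#' @param test_scores data.frame of raw test scores, one column per test.
#' @param domain_spec named list; each element is a named numeric vector
#'   mapping member test names to an orientation (+1 higher-is-better,
#'   -1 lower-is-better). See [default_domain_spec()].
#' @return data.frame of per-subject domain z-scores, one column per
#'   domain.
#' @export
composite_domain_score <- function(test_scores, domain_spec = default_domain_spec()) {
  test_scores <- as.data.frame(test_scores)
  used <- unique(unlist(lapply(domain_spec, names)))
  missing <- setdiff(used, colnames(test_scores))
  if (length(missing))
    stop("tests missing from data: ", paste(missing, collapse = ", "))
  zs <- lapply(used, function(tn) {
    v <- test_scores[[tn]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("test has zero standard deviation: ", tn)
    (v - mean(v)) / s
  })
  names(zs) <- used
  out <- lapply(domain_spec, function(spec) {
    zmat <- vapply(names(spec), function(tn) zs[[tn]] * spec[[tn]],
                   numeric(nrow(test_scores)))
    rowMeans(matrix(zmat, nrow = nrow(test_scores)))
  })
  as.data.frame(out)
}

#' Default cognitive domain composition
#'
#' Five domains built from standard neuropsychological tests: episodic
#' memory (delayed-recall scores), visuospatial function (clock drawing,
#' figure copy), information processing speed (timed tests, sign-flipped),
#' language (fluency, naming), and executive function (backward digit
#' span plus timed set-shifting/interference tests, the latter
#' sign-flipped).
#'
#' @return named list suitable for [composite_domain_score()].
#' @export
default_domain_spec <- function() {
  list(episodic_memory = c(avlt_dr = 1, wms_vr_dr = 1),
       visuospatial = c(cdt = 1, vr_c = 1),
       processing_speed = c(tmt_a = -1, stroop_a = -1, stroop_b = -1),
       language = c(cvf = 1, bnt = 1),
       executive = c(dst_backward = 1, tmt_b = -1, stroop_c = -1))
}

## internal: shared StatResult constructor
stat_result <- function(statistic, df, p, method, effect = NA_real_, q = NA_real_) {
  structure(list(statistic = unname(statistic), df = df, p = unname(p),
                 q = q, effect = unname(effect), method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g%s%s\n",
              x$method, x$statistic, paste(x$df, collapse = ","), x$p,
              if (!is.na(x$effect)) sprintf(", effect = %.4f", x$effect) else "",
              if (!is.na(x$q)) sprintf(", q = %.4g", x$q) else ""))
  invisible(x)
}

## internal: error on singular design, naming the aliased columns
check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("singular design matrix; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(qx)
}

## internal: design matrix for outcome ~ covariates (+ group dummies)
build_design <- function(n, covariates) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cdf <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = cdf)
}

#' Covariate-adjusted group comparison
#'
#' The three test families used for cohort tables: `"ancova"` fits a linear
#' model of the outcome on covariates plus group indicators and reports the
#' F-test of the group block (with no covariates this is one-way ANOVA);
#' `"kruskal_wallis"` is the rank-based one-way test (covariates, if
#' supplied, are ignored with a warning); `"chi_square"` is Pearson's
#' chi-squared on the group x outcome contingency table without continuity
#' correction (documented choice, so 2x2 tables match the plain formula).
#'
#' @param outcome per-subject outcome (numeric, or categorical for
#'   `chi_square`).
#' @param group per-subject group labels (>= 2 groups).
#' @param covariates optional data.frame of per-subject covariates.
#' @param method one of `"ancova"`, `"kruskal_wallis"`, `"chi_square"`.
#' @return a `stat_result` with the test statistic, degrees of freedom and
#'   p-value.
#' @export
group_compare <- function(outcome, group,
                          covariates = NULL,
                          method = c("ancova", "kruskal_wallis", "chi_square")) {
  method <- match.arg(method)
  group <- factor(group)
  stopifnot(length(outcome) == length(group), nlevels(group) >= 2)

  if (method == "kruskal_wallis") {
    if (!is.null(covariates))
      warning("kruskal_wallis ignores covariates")
    kt <- stats::kruskal.test(outcome, group)
    return(stat_result(kt$statistic, unname(kt$parameter), kt$p.value,
                       "Kruskal-Wallis"))
  }
  if (method == "chi_square") {
    tab <- table(group, outcome)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(stat_result(ct$statistic, unname(ct$parameter), ct$p.value,
                       "chi-squared"))
  }
  ## ANCOVA: F-test of the group block given the covariates
  y <- as.numeric(outcome)
  X0 <- build_design(length(y), covariates)
  G <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  X1 <- cbind(X0, G)
  check_full_rank(X1)
  fit0 <- stats::lm.fit(X0, y)
  fit1 <- stats::lm.fit(X1, y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df_g <- ncol(G)
  df_res <- length(y) - ncol(X1)
  f <- ((rss0 - rss1) / df_g) / (rss1 / df_res)
  p <- stats::pf(f, df_g, df_res, lower.tail = FALSE)
  stat_result(f, c(df_g, df_res), p,
              if (is.null(covariates)) "ANOVA" else "ANCOVA")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: sort the m p-values ascending, find the largest i
#' with `p_(i) <= (i/m) * q_level`, and declare tests 1..i significant.
#' Adjusted values are the standard monotone (cumulative-minimum)
#' construction, computed by [stats::p.adjust()]; the significance mask is
#' `adjusted <= q_level`, which is exactly the step-up rule.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q_level FDR level (default 0.05; the nodal-metric convention in
#'   this pipeline is 0.01).
#' @return list with `significant` (logical mask, input order) and
#'   `adjusted` (BH-adjusted p-values).
#' @export
fdr_correct <- function(pvalues, q_level = 0.05) {
  if (length(pvalues) == 0)
    return(list(significant = logical(0), adjusted = numeric(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(significant = adj <= q_level, adjusted = adj)
}

#' Covariate-adjusted pairwise post-hoc contrast
#'
#' From the same linear model as [group_compare()] (cell-means group coding
#' plus covariates), the contrast between two named groups: its estimate
#' equals the difference of covariate-adjusted group means, tested with a
#' t-statistic on the residual degrees of freedom. Reported without
#' additional family-wise correction (raw pairwise p-values), flagged in
#' the method string.
#'
#' @inheritParams group_compare
#' @param pair character vector of two group labels to contrast
#'   (first minus second).
#' @return a `stat_result`; `effect` holds the adjusted mean difference.
#' @export
posthoc_pairwise <- function(outcome, group, pair, covariates = NULL) {
  group <- factor(group)
  if (!all(pair %in% levels(group)))
    stop("unknown group label(s): ",
         paste(setdiff(pair, levels(group)), collapse = ", "))
  stopifnot(length(pair) == 2)
  y <- as.numeric(outcome)
  G <- stats::model.matrix(~ 0 + group)
  colnames(G) <- levels(group)
  Xc <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE]
  X <- cbind(G, Xc)
  check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  df_res <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(qr.R(fit$qr))
  cw <- stats::setNames(numeric(ncol(X)), colnames(X))
  cw[pair[1]] <- 1; cw[pair[2]] <- -1
  ## coefficients from lm.fit follow the pivoted column order
  piv <- fit$qr$pivot
  est <- sum(cw[piv] * fit$coefficients)
  se <- sqrt(sigma2 * as.numeric(t(cw[piv]) %*% XtXinv %*% cw[piv]))
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  stat_result(tval, df_res, p, "pairwise contrast (uncorrected)", effect = est)
}

#' Regression of a cognitive score on a network metric
#'
#' OLS of the (standardized) outcome on the standardized metric plus
#' covariates; reports the standardized coefficient of the metric and its
#' t-test p-value.
#'
#' @param outcome per-subject cognitive (domain) score.
#' @param metric per-subject network metric value.
#' @param covariates optional data.frame of adjustment covariates.
#' @return a `stat_result`; `effect` is the standardized beta of the
#'   metric, `statistic` its t value.
#' @export
regress_metric_on_cognition <- function(outcome, metric, covariates = NULL) {
  n <- length(outcome)
  stopifnot(length(metric) == n)
  ys <- as.numeric(scale(outcome))
  ms <- as.numeric(scale(metric))
  Xc <- build_design(n, covariates)
  X <- cbind(Xc, metric = ms)
  if (n <= ncol(X) + 1) stop("too few subjects for the number of predictors")
  check_full_rank(X)
  fit <- stats::lm.fit(X, ys)
  df_res <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(qr.R(fit$qr))
  piv <- fit$qr$pivot
  j <- which(colnames(X)[piv] == "metric")
  beta <- fit$coefficients[j]
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  stat_result(tval, df_res, p, "metric regression", effect = beta)
}
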