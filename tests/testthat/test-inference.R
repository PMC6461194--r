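test_that("composite domain scores standardize, orient and average correctly", {
  set.seed(51)
  n <- 40
  raw <- data.frame(avlt_dr = rnorm(n, 6, 2), wms_vr_dr = rnorm(n, 7, 3),
                    cdt = rnorm(n, 3.8, 0.5), vr_c = rnorm(n, 13, 1.5),
                    tmt_a = rnorm(n, 50, 10), stroop_a = rnorm(n, 17, 4),
                    stroop_b = rnorm(n, 22, 5), cvf = rnorm(n, 17, 3),
                    bnt = rnorm(n, 50, 5), dst_backward = rnorm(n, 5, 1),
                    tmt_b = rnorm(n, 90, 25), stroop_c = rnorm(n, 31, 7))
  dom <- composite_domain_score(raw)
  expect_setequal(colnames(dom), c("episodic_memory", "visuospatial",
                                   "processing_speed", "language", "executive"))
  ## domain scores are averages of whole-sample z-scores: mean ~ 0
  expect_true(all(abs(colMeans(dom)) < 1e-10))

  ## a subject exactly at the sample mean on every test scores 0 everywhere
  raw2 <- raw
  raw2[1, ] <- colMeans(raw[-1, ])
  ## recenter so subject 1 is at the *full-sample* mean of each test
  for (cn in colnames(raw2)) raw2[[cn]][1] <- mean(raw2[[cn]][-1])
  d2 <- composite_domain_score(raw2)
  expect_true(all(abs(d2[1, ]) < 0.2))  # near the center, not exact (n-1 shift)

  ## two-member domain with z = +1 and -1 averages to 0
  toy <- data.frame(t1 = c(rep(0, 9), 3), t2 = c(rep(0, 9), 3))
  spec <- list(d = c(t1 = 1, t2 = -1))
  expect_equal(composite_domain_score(toy, spec)$d, rep(0, 10))

  ## slowest TMT-A subject gets the most negative processing-speed score
  raw3 <- raw
  raw3$tmt_a[5] <- max(raw3$tmt_a) + 100
  d3 <- composite_domain_score(raw3,
                               list(processing_speed = c(tmt_a = -1)))
  expect_equal(which.min(d3$processing_speed), 5L)

  ## affine rescaling of any raw test leaves domain scores unchanged
  raw4 <- raw
  raw4$tmt_a <- raw4$tmt_a * 60 + 1000
  expect_equal(composite_domain_score(raw4), dom, tolerance = 1e-10)

  expect_error(composite_domain_score(data.frame(t1 = rep(1, 5)),
                                      list(d = c(t1 = 1))), "t1")
  expect_error(composite_domain_score(raw, list(d = c(nope = 1))), "nope")
})

test_that("group comparisons match base-R reference fits", {
  set.seed(52)
  n <- 80
  g <- rep(c("A", "B", "C", "D"), each = n / 4)
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.5 * (g == "B") + 0.2 * covs$age

  ## ANCOVA equals the nested-model anova() on lm fits
  res <- group_compare(y, g, covs, "ancova")
  f0 <- lm(y ~ age + sex, data = covs)
  f1 <- lm(y ~ age + sex + factor(g), data = cbind(covs, g = g))
  ref <- anova(f0, f1)
  expect_equal(res$statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(res$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(res$df, c(3, n - 6))

  ## without covariates the ANCOVA route reduces to plain one-way ANOVA
  res0 <- group_compare(y, g, method = "ancova")
  ref0 <- summary(aov(y ~ factor(g)))[[1]]
  expect_equal(res0$statistic, ref0$`F value`[1], tolerance = 1e-8)

  ## Kruskal-Wallis and chi-square delegate to the standard definitions
  kw <- group_compare(y, g, method = "kruskal_wallis")
  expect_equal(kw$statistic, unname(kruskal.test(y, factor(g))$statistic))
  expect_warning(group_compare(y, g, covs, "kruskal_wallis"), "ignores")

  bin <- rep(c("yes", "no"), c(10, 10))
  g2 <- rep(c("A", "B"), c(10, 10))
  cs <- group_compare(bin, g2, method = "chi_square")
  expect_equal(cs$statistic, 20)  # [[10,0],[0,10]] without continuity correction

  ## singular designs are rejected with the collinear column named
  covs_bad <- data.frame(age = covs$age, age2 = covs$age * 2)
  expect_error(group_compare(y, g, covs_bad, "ancova"), "age2")
})

test_that("null group comparisons produce uniform p-values", {
  set.seed(53)
  ps <- replicate(1000, {
    g <- rep(c("A", "B", "C", "D"), each = 10)
    group_compare(rnorm(40), g, method = "ancova")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH step-up control matches the literal procedure", {
  expect_equal(fdr_correct(rep(0.5, 10), 0.01)$significant, rep(FALSE, 10))
  ## the step-up rescue: i = 4 admits p = 0.039 and 0.041
  r <- fdr_correct(c(0.001, 0.008, 0.039, 0.041), 0.05)
  expect_equal(r$significant, rep(TRUE, 4))
  expect_equal(fdr_correct(0.005, 0.01)$significant, TRUE)
  expect_identical(fdr_correct(numeric(0))$significant, logical(0))

  set.seed(54)
  for (rep in 1:50) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_correct(p, q)$significant, bh_stepup_oracle(p, q))
  }
})

test_that("post-hoc contrasts equal adjusted mean differences with correct power", {
  set.seed(55)
  n <- 60
  g <- rep(c("A", "B", "C"), each = n / 3)
  covs <- data.frame(age = rnorm(n))
  y <- rnorm(n) + 0.8 * covs$age + 1.0 * (g == "B")

  res <- posthoc_pairwise(y, g, c("B", "A"), covs)
  ## oracle: covariate-adjusted means from a standard lm fit
  fit <- lm(y ~ 0 + factor(g) + age, data = cbind(covs, g = g))
  adj <- coef(fit)[c("factor(g)B", "factor(g)A")]
  expect_equal(res$effect, unname(adj[1] - adj[2]), tolerance = 1e-10)
  ## and the t-test matches summary() on the releveled model
  fit2 <- lm(y ~ factor(g, levels = c("A", "B", "C")) + age, cbind(covs, g = g))
  sm <- summary(fit2)$coefficients[2, ]
  expect_equal(res$statistic, unname(sm["t value"]), tolerance = 1e-8)
  expect_equal(res$p, unname(sm["Pr(>|t|)"]), tolerance = 1e-8)

  ## identical groups: no signal
  y0 <- rep(rnorm(n / 3), 3)
  r0 <- posthoc_pairwise(y0, g, c("A", "B"))
  expect_lt(abs(r0$statistic), 1e-8)
  expect_gt(r0$p, 0.999)

  ## planted 1 SD shift at n = 25/group detected in >= 90% of simulations
  rej <- replicate(200, {
    gg <- rep(c("A", "B"), each = 25)
    yy <- rnorm(50) + 1.0 * (gg == "B")
    posthoc_pairwise(yy, gg, c("B", "A"))$p < 0.05
  })
  expect_gte(mean(rej), 0.90)

  expect_error(posthoc_pairwise(y, g, c("A", "Z")), "Z")
})

test_that("metric-cognition regression reports calibrated standardized betas", {
  set.seed(56)
  x <- rnorm(100)
  r1 <- regress_metric_on_cognition(x, x)
  expect_equal(r1$effect, 1, tolerance = 1e-8)
  expect_lt(r1$p, 1e-12)

  ## null: estimates centered on zero
  betas <- replicate(500, regress_metric_on_cognition(rnorm(50), rnorm(50))$effect)
  expect_lt(abs(mean(betas)), 0.02)

  ## planted standardized beta = 0.5 recovered without bias
  b05 <- replicate(500, {
    m <- rnorm(200)
    y <- 0.5 * scale(m) + rnorm(200, sd = sqrt(0.75))
    regress_metric_on_cognition(y, m)$effect
  })
  expect_lt(abs(mean(b05) - 0.5), 0.03)

  ## matches lm on standardized variables, with covariates
  covs <- data.frame(age = rnorm(100), edu = rnorm(100))
  y <- 0.4 * scale(x) + 0.3 * covs$age + rnorm(100, sd = 0.6)
  r <- regress_metric_on_cognition(y, x, covs)
  fit <- lm(scale(y) ~ age + edu + scale(x), data = covs)
  expect_equal(r$effect, unname(coef(fit)["scale(x)"]), tolerance = 1e-8)
  expect_error(regress_metric_on_cognition(rnorm(4), rnorm(4),
                                           data.frame(a = rnorm(4), b = rnorm(4))))
})
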