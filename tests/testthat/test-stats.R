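test_that("IQR fencing matches the quartile oracle and conserves points", {
  # {1..10}: Q1 = 3.25, Q3 = 7.75, IQR = 4.5 -> fences [-10.25, 21.25]
  r <- remove_outliers(1:10)
  expect_equal(r$fences, c(3.25 - 3 * 4.5, 7.75 + 3 * 4.5))
  expect_equal(r$values, 1:10)
  expect_length(r$removed, 0)

  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2 -> upper fence 10 -> 100 removed
  r2 <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(r2$fences, c(-4, 10))
  expect_equal(r2$removed, 5L)
  expect_equal(r2$values, c(1, 2, 3, 4))

  # constant vector: IQR 0, fence equals the value, nothing removed
  r3 <- remove_outliers(rep(7, 6))
  expect_length(r3$removed, 0)

  expect_error(remove_outliers(c(1, 2, 3)), "4")

  # removed + retained = input; retained all within fences of the full input
  set.seed(10)
  for (i in 1:20) {
    x <- rt(30, df = 2)
    r <- remove_outliers(x, k = 1.5)
    expect_equal(length(r$values) + length(r$removed), length(x))
    expect_true(all(r$values >= r$fences[1] & r$values <= r$fences[2]))
    expect_true(all(x[r$removed] < r$fences[1] | x[r$removed] > r$fences[2]))
  }
})

test_that("ANCOVA matches a from-scratch normal-equations oracle", {
  set.seed(11)
  g <- rep(c("A", "B", "C"), times = c(7, 6, 8))
  y <- rnorm(21) + c(A = 0, B = 0.5, C = 1)[g]
  x <- rnorm(21)
  res <- ancova_oneway(y, g, x)

  # independent matrix-algebra oracle: explicit projections
  X1 <- cbind(1, x, model.matrix(~ g)[, -1])
  X0 <- cbind(1, x)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  ssg <- rss(X0) - rss(X1)
  sse <- rss(X1)
  Fo <- (ssg / 2) / (sse / (21 - 4))
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$eta_p2, ssg / (ssg + sse), tolerance = 1e-10)
  expect_equal(res$p, pf(Fo, 2, 17, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("identical group distributions give F near zero", {
  y0 <- rnorm(15)
  y <- rep(y0, 3)
  g <- rep(c("A", "B", "C"), each = 15)
  res <- ancova_oneway(y, g, rep(rnorm(15), 3))
  expect_lt(res$F, 1e-20)
})

test_that("collinear covariate errors; zero-effect covariate reduces to ANOVA", {
  y <- rnorm(20)
  g <- rep(c("A", "B"), each = 10)
  expect_error(ancova_oneway(y, g, as.numeric(g == "A")), "collinear")

  # covariate orthogonalized to outcome and groups: identical sums of squares,
  # F differs only by the structural error-df factor
  set.seed(12)
  g <- rep(c("A", "B", "C"), each = 10)
  y <- rnorm(30) + as.numeric(factor(g))
  x0 <- rnorm(30)
  x <- lm(x0 ~ y + factor(g))$residuals
  a_cov <- ancova_oneway(y, g, x)
  a_plain <- ancova_oneway(y, g)
  expect_equal(a_cov$ss_group, a_plain$ss_group, tolerance = 1e-10)
  expect_equal(a_cov$ss_error, a_plain$ss_error, tolerance = 1e-10)
  expect_equal(a_cov$F / a_plain$F, a_cov$df[2] / a_plain$df[2], tolerance = 1e-8)
})

test_that("ANCOVA converges to ANOVA as the covariate effect vanishes", {
  set.seed(13)
  g <- rep(c("A", "B", "C"), each = 20)
  y <- rnorm(60) + c(A = 0, B = 0.4, C = 0.8)[g]
  diffs <- vapply(c(1, 0.1, 0.01), function(b) {
    x <- scale(lm(rnorm(60) ~ y)$residuals) + b * scale(y)  # correlation shrinks with b
    abs(ancova_oneway(y, g, as.numeric(x))$F - ancova_oneway(y, g)$F)
  }, numeric(1))
  expect_lt(diffs[3], diffs[1])
})

test_that("Tukey-Kramer p-values match TukeyHSD and d is antisymmetric", {
  set.seed(14)
  y <- rnorm(45) + rep(c(0, 0.8, 1.6), times = c(20, 10, 15))
  g <- rep(c("A", "B", "C"), times = c(20, 10, 15))
  res <- tukey_posthoc_effects(y, g)
  ref <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  for (pr in rownames(ref)) {
    lv <- strsplit(pr, "-")[[1]]
    mine <- res[res$pair %in% c(paste(lv[1], lv[2], sep = "-"),
                                paste(lv[2], lv[1], sep = "-")), ]
    expect_equal(mine$p, ref[pr, "p adj"], tolerance = 1e-8)
  }
  # relabeling invariance and antisymmetry of d
  perm <- c(A = "C", B = "A", C = "B")
  res2 <- tukey_posthoc_effects(y, perm[g])
  expect_equal(sort(res$p), sort(res2$p), tolerance = 1e-12)
  ab <- res$d[res$pair == "A-B"]
  res_rev <- tukey_posthoc_effects(y, factor(g, levels = c("B", "A", "C")))
  expect_equal(res_rev$d[res_rev$pair == "B-A"], -ab)
})

test_that("Tukey null and definitional d cases behave", {
  y0 <- rnorm(12)
  res <- tukey_posthoc_effects(c(y0, y0), rep(c("A", "B"), each = 12))
  expect_equal(res$d, 0)
  expect_gt(res$p, 0.999)

  # means 1 and 2, pooled SD 1 -> d = 1 (construct exactly)
  a <- c(0, 2) + 1 - 1  # mean 1, sd sqrt(2)... use explicit values instead
  a <- c(1 - sqrt(0.5), 1 + sqrt(0.5))  # mean 1, sd 1
  b <- c(2 - sqrt(0.5), 2 + sqrt(0.5))  # mean 2, sd 1
  res2 <- tukey_posthoc_effects(c(a, b), rep(c("A", "B"), each = 2))
  expect_equal(res2$d[1], -1)

  # singleton group flagged undefined
  res3 <- tukey_posthoc_effects(c(1, 2, 3, 9), c("A", "A", "A", "B"))
  expect_true(is.na(res3$p))
})

test_that("clinical correlations gate on normality and support partialling", {
  set.seed(15)
  x <- rnorm(60)
  r1 <- correlate_clinical(x, 2 * x)
  expect_equal(r1$method, "pearson")
  expect_equal(r1$estimate, 1)

  xh <- rt(60, df = 1)
  r2 <- correlate_clinical(xh, exp(pmin(xh, 20)))
  expect_equal(r2$method, "spearman")
  expect_equal(r2$estimate, 1)

  # both variables driven by the covariate -> partial coefficient near 0
  z <- rnorm(500)
  r3 <- correlate_clinical(z + rnorm(500, 0, 0.5), z + rnorm(500, 0, 0.5),
                           covariate = z)
  expect_lt(abs(r3$estimate), 0.1)
  expect_true(r3$partial)

  # zero variance -> undefined with explanation, not an error
  r4 <- correlate_clinical(rep(1, 10), rnorm(10))
  expect_true(is.na(r4$estimate))
  expect_error(correlate_clinical(rnorm(3), rnorm(3)), "4")
})

test_that("feature-wise comparison table flags by omnibus p", {
  sim <- small_cohort()
  fm <- simulated_feature_matrix(sim)
  cmp <- compare_all_features(fm)
  expect_equal(nrow(cmp), 10L)
  expect_equal(cmp$feature, feature_names())
  expect_true(all(cmp$p >= 0 & cmp$p <= 1, na.rm = TRUE))
  expect_true(all(cmp$eta_p2 >= 0 & cmp$eta_p2 <= 1, na.rm = TRUE))
  expect_equal(cmp$significant, cmp$p < 0.05)
  expect_equal(nrow(cmp$posthoc[[1]]), 3L)
})
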