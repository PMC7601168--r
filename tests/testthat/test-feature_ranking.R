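test_that("pooled covariance is the sample-size-weighted average", {
  C0 <- matrix(c(2, 1, 1, 3), 2, 2)
  expect_equal(pooled_covariance(C0, C0, 7, 3), C0)
  expect_equal(pooled_covariance(2, 6, 5, 5)[1, 1], 4)
  expect_equal(pooled_covariance(0, 4, 3, 1)[1, 1], 1)
  expect_error(pooled_covariance(diag(2), diag(3), 2, 2), "shapes")
  expect_error(pooled_covariance(2, 2, 0, 5), "positive")
})

test_that("univariate separation matches the closed form on hand inputs", {
  expect_equal(fisher_separation(c(1, 1, 3, 3), c(4, 4, 6, 6)), 9)
  # means 1 and 5, population variances 1 and 1, pooled 1 -> 16
  expect_equal(fisher_separation(c(0, 0, 2, 2), c(4, 4, 6, 6)), 16)
  expect_equal(fisher_separation(c(2, 3, 2, 3), c(2, 3, 2, 3)), 0)
  expect_error(fisher_separation(1, c(1, 2)), "samples")
})

test_that("separation is invariant to affine rescaling and degenerate-safe", {
  set.seed(14)
  x1 <- rnorm(40, 1, 2); x2 <- rnorm(40, 4, 1.5)
  d0 <- fisher_separation(x1, x2)
  expect_equal(fisher_separation(2 * x1, 2 * x2), d0)
  for (a in c(0.3, 5)) for (b in c(-7, 2)) {
    expect_equal(fisher_separation(a * x1 + b, a * x2 + b), d0,
                 tolerance = 1e-12)
  }
  expect_equal(fisher_separation(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_warning(inf <- fisher_separation(c(5, 5, 5), c(7, 7, 7)), "infinite")
  expect_equal(inf, Inf)
})

test_that("the multivariate discriminant reduces to the univariate score", {
  set.seed(15)
  x1 <- matrix(rnorm(50, 0, 1)); x2 <- matrix(rnorm(60, 2, 1.3))
  m <- lda_model(x1, x2)
  expect_equal(m$delta2, fisher_separation(x1[, 1], x2[, 1]))
  # two correlated features: delta2 via solve() equals beta'(mu1-mu2) >= 0
  X1 <- cbind(rnorm(80), rnorm(80)); X1[, 2] <- X1[, 2] + 0.5 * X1[, 1]
  X2 <- sweep(cbind(rnorm(80), rnorm(80)), 2, c(1.5, 0.5), `+`)
  mm <- lda_model(X1, X2)
  expect_gte(mm$delta2, 0)
  expect_equal(mm$delta2,
               drop(t(mm$mu1 - mm$mu2) %*% solve(mm$C) %*% (mm$mu1 - mm$mu2)))
  expect_equal(mm$score(mm$mu1) - mm$score(mm$mu2), mm$delta2)
})

test_that("ranking printed discriminant scores reproduces the published order", {
  scores <- c(variance = 4, sum_average = 3.7, idm = 3, sum_variance = 2.7,
              entropy = 2.1, diff_entropy = 1.7, sum_entropy = 1.4,
              correlation = 1.1, contrast = 0, info_correlation = 0)
  # feed them in feature-index order so the tie-break is exercised
  shuffled <- scores[c("contrast", "correlation", "variance", "idm",
                       "sum_average", "sum_variance", "sum_entropy",
                       "entropy", "diff_entropy", "info_correlation")]
  r <- rank_features(shuffled)
  expect_equal(r$feature,
               c("variance", "sum_average", "idm", "sum_variance", "entropy",
                 "diff_entropy", "sum_entropy", "correlation", "contrast",
                 "info_correlation"))
  expect_equal(feature_display_names(r$feature),
               c("Variance", "Sum average", "Inverse difference moment",
                 "Sum variance", "Entropy", "Difference entropy",
                 "Sum entropy", "Correlation", "Contrast",
                 "Measure of co-relation"))
  expect_true(all(diff(r$score) <= 0))
})

test_that("ranking a feature table finds the one discriminative feature", {
  set.seed(16)
  n <- 60
  tab <- as.data.frame(setNames(
    lapply(oratex:::haralick_feature_names, function(f) rnorm(n)),
    oratex:::haralick_feature_names))
  tab$label <- rep(c("standard", "anomalous"), n / 2)
  tab$sum_entropy <- tab$sum_entropy + ifelse(tab$label == "anomalous", 8, 0)
  r <- rank_features(tab)
  expect_equal(r$feature[1], "sum_entropy")
  expect_setequal(r$feature, oratex:::haralick_feature_names)

  tab$label <- "standard"
  expect_error(rank_features(tab), "both classes")
})

test_that("equal scores fall back to feature-index order", {
  scores <- setNames(rep(0, 10), oratex:::haralick_feature_names)
  r <- rank_features(scores)
  expect_equal(r$feature, oratex:::haralick_feature_names)
})

test_that("select_top honours the ranking and validates k", {
  scores <- c(variance = 4, sum_average = 3.7, idm = 3, sum_variance = 2.7,
              entropy = 2.1, diff_entropy = 1.7, sum_entropy = 1.4,
              correlation = 1.1, contrast = 0, info_correlation = 0)
  r <- rank_features(scores)
  top8 <- select_top(r, 8)
  expect_length(top8, 8)
  expect_false(any(c("contrast", "info_correlation") %in% top8))
  expect_equal(select_top(r, 1), "variance")
  expect_length(select_top(r, 10), 10)
  expect_error(select_top(r, 0), "out of range")
  expect_error(select_top(r, 11), "out of range")
})
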