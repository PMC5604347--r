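test_that("overlap ratio matches its printed definition", {
  gt <- disk_mask(50, 50, c(25, 25), 10)
  expect_equal(overlap_ratio(gt, gt), 1.0)

  far <- disk_mask(50, 50, c(10, 10), 5)
  far2 <- disk_mask(50, 50, c(40, 40), 5)
  expect_equal(overlap_ratio(far, far2), 0.0)

  # half-covered 10x10 square
  gt <- matrix(FALSE, 20, 20); gt[6:15, 6:15] <- TRUE
  cmsk <- matrix(FALSE, 20, 20); cmsk[6:15, 6:10] <- TRUE
  expect_equal(overlap_ratio(cmsk, gt), 0.5)

  expect_error(overlap_ratio(gt, matrix(FALSE, 20, 20)), "empty")
})

test_that("Ov ignores transferred-mask pixels outside ground truth", {
  gt <- disk_mask(60, 60, c(30, 30), 10)
  cmsk <- disk_mask(60, 60, c(30, 30), 10)
  ov0 <- overlap_ratio(cmsk, gt)
  cmsk_big <- disk_mask(60, 60, c(30, 30), 25)   # superset of gt
  expect_equal(overlap_ratio(cmsk_big, gt), ov0)
  # and is monotone as CMSK grows toward covering GT
  ovs <- sapply(c(4, 6, 8, 10), function(r) overlap_ratio(disk_mask(60, 60, c(30, 30), r), gt))
  expect_true(all(diff(ovs) >= 0))
})

test_that("tumor cell count error matches its printed definition", {
  expect_equal(tumor_count_error(37, 37), 0.0)
  expect_equal(tumor_count_error(0, 50), 1.0)
  expect_equal(tumor_count_error(15, 20), 0.25)
  # symmetric in sign of the miscount, scale-free in n_gt
  expect_equal(tumor_count_error(25, 20), tumor_count_error(15, 20))
  expect_equal(tumor_count_error(150, 200), tumor_count_error(15, 20))
  expect_error(tumor_count_error(5, 0), "positive")
})

test_that("pearson matches the direct covariance formula and its invariances", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(1, 2, 4, 5); y <- c(1, 3, 3, 6)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson(2 * x + 7, y), pearson(x, y), tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1, 1), y), "constant")
})

test_that("Bland-Altman reports mean, limits and one-sided p", {
  a <- c(3, 5, 2, 8)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$p_one_sided, 0.5)

  # degenerate constant positive difference
  ba1 <- bland_altman(a + 1, a)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(ba1$p_one_sided, 0)
  expect_equal(bland_altman(a - 1, a)$p_one_sided, 1)

  # two-pass oracle on d = (2, -1, 3, 0, 1)
  b <- c(0, 0, 0, 0, 0); a2 <- c(2, -1, 3, 0, 1)
  ba <- bland_altman(a2, b)
  m <- sum(a2) / 5
  s <- sqrt(sum((a2 - m)^2) / 4)
  expect_equal(ba$mean_diff, 1.0)
  expect_equal(ba$sd_diff, s, tolerance = 1e-12)
  expect_equal(ba$loa_low, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_high, m + 1.96 * s, tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
  # p from t distribution, one-sided
  tt <- m / (s / sqrt(5))
  expect_equal(ba$p_one_sided, pt(tt, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "lengths differ")
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  res <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(res$df1, 1); expect_equal(res$df2, 4)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "zero within-group")

  set.seed(3)
  gs <- list(rnorm(7), rnorm(5, 1), rnorm(9, -0.5))
  res <- anova_oneway(gs)
  x <- unlist(gs); gm <- mean(x)
  ssb <- sum(sapply(gs, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(gs, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / 2) / (ssw / (length(x) - 3))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  # cross-check against the standard fitter
  expect_equal(res$F,
               unname(summary(aov(x ~ factor(rep(1:3, lengths(gs)))))[[1]]$`F value`[1]),
               tolerance = 1e-10)
})

test_that("mask agreement bundles Ov, TCe and symmetric measures", {
  gt <- disk_mask(100, 100, c(50, 50), 20)
  cmsk <- disk_mask(100, 100, c(50, 55), 20)
  cells <- data.frame(row = c(50, 50, 50, 10), col = c(32, 50, 73, 10),
                      label = c("tumor", "tumor", "tumor", "tumor"))
  ag <- mask_agreement(cmsk, gt, cells)
  expect_equal(ag$Ov, overlap_ratio(cmsk, gt))
  expect_equal(ag$n_cells_gt, 2)    # cells at cols 32, 50 under gt
  expect_equal(ag$n_cells_cmsk, 2)  # cells at cols 50, 73 under cmsk
  expect_equal(ag$TCe, 0)
  expect_lte(ag$jaccard, ag$dice)
})
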