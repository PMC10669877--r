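test_that("paired comparisons report signed differences and p-values", {
  # identical vectors: difference 0, p reported as 1
  df0 <- tibble::tibble(subject = rep(1:5, 2),
                        condition = rep(c("EC", "EO"), each = 5),
                        value = rep(c(3, 4, 5, 6, 7), 2))
  r0 <- paired_compare(df0)
  expect_equal(r0$mean_difference, 0)
  expect_equal(r0$p_value, 1)

  # constant +2 shift with tiny noise: difference ~ 2, p < 0.001
  set.seed(61)
  base <- rnorm(10, 10)
  df2 <- tibble::tibble(subject = rep(1:10, 2),
                        condition = rep(c("EC", "EO"), each = 10),
                        value = c(base, base + 2 + rnorm(10, 0, 0.01)))
  r2 <- paired_compare(df2)
  expect_equal(r2$mean_difference, 2, tolerance = 0.02)
  expect_lt(r2$p_value, 0.001)
  expect_true(r2$sig_001)

  # sign convention: condition2 - condition1, so reversing flips the sign
  r2r <- paired_compare(df2, conditions = c("EO", "EC"))
  expect_equal(r2r$mean_difference, -r2$mean_difference)

  # unpaired data errors
  expect_error(paired_compare(df2[-1, ]), "unpaired")
})

test_that("Tukey HSD flags only genuinely shifted groups and matches multcomp", {
  set.seed(62)
  # identical groups: all adjusted p near 1
  dfe <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 10),
                        value = rep(rnorm(10), 3) + rnorm(30, 0, 1e-6))
  expect_true(all(tukey_hsd(dfe)$p_value > 0.9))

  # one group shifted by 5 SDs
  dfs <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 12),
                        value = c(rnorm(12), rnorm(12), rnorm(12) + 5))
  rs <- tukey_hsd(dfs)
  involved <- rs$condition_1 == "c" | rs$condition_2 == "c"
  expect_true(all(rs$sig_05[involved]))
  expect_true(all(!rs$sig_05[!involved]))

  # textbook one-way fixture against an independent implementation
  skip_if_not_installed("multcomp")
  df3 <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 8),
                        value = c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 2.5)))
  ours <- tukey_hsd(df3)
  fit <- stats::aov(value ~ condition,
                    data = transform(as.data.frame(df3), condition = factor(condition)))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Tukey"))
  ci <- confint(gl)$confint
  expect_equal(unname(ours$mean_difference), unname(ci[, "Estimate"]),
               tolerance = 1e-8)
  expect_equal(unname(ours$p_value),
               as.numeric(summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues),
               tolerance = 0.02, ignore_attr = TRUE) # multcomp p-values are simulation-based
  expect_error(tukey_hsd(dfe[dfe$condition == "a", ]), "at least 2")
})

test_that("adjusted p-values are never smaller than unadjusted pairwise p", {
  set.seed(63)
  df <- tibble::tibble(condition = rep(c("a", "b", "c", "d"), each = 10),
                       value = rnorm(40) + rep(c(0, 0.3, 0.6, 0.9), each = 10))
  tk <- tukey_hsd(df)
  # unadjusted two-sided p from the same pooled-variance statistic the HSD
  # procedure studentises
  fit <- stats::aov(value ~ factor(condition), data = as.data.frame(df))
  mse <- sum(stats::resid(fit)^2) / fit$df.residual
  for (i in seq_len(nrow(tk))) {
    se <- sqrt(mse * (1 / 10 + 1 / 10))
    raw <- 2 * stats::pt(-abs(tk$mean_difference[i] / se), fit$df.residual)
    expect_gte(tk$p_value[i] + 1e-10, raw)
  }
})

test_that("type-I error is calibrated under label permutation", {
  set.seed(64)
  n_reps <- 400
  hits <- 0
  for (i in seq_len(n_reps)) {
    df <- tibble::tibble(subject = rep(1:10, 2),
                         condition = rep(c("x", "y"), each = 10),
                         value = rnorm(20))
    hits <- hits + (paired_compare(df)$p_value < 0.05)
  }
  expect_lt(abs(hits / n_reps - 0.05), 0.03)
})

test_that("compare_conditions stacks paired and Tukey rows per metric", {
  set.seed(65)
  per_subject <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:8), 3),
    condition = rep(c("EC", "EO", "WM"), each = 8),
    hvp_d = rnorm(24, rep(c(20, 40, 18), each = 8), 3),
    hvp_a = rnorm(24, rep(c(100, 160, 90), each = 8), 20)
  )
  res <- compare_conditions(per_subject)
  expect_setequal(unique(res$test), c("paired_t", "tukey_hsd"))
  expect_setequal(unique(res$metric), c("hvp_d", "hvp_a"))
  # 3 pairs per metric per test
  expect_equal(sum(res$test == "paired_t" & res$metric == "hvp_d"), 3)
  ec_eo <- res[res$test == "paired_t" & res$metric == "hvp_d" &
                 res$condition_1 == "EC" & res$condition_2 == "EO", ]
  expect_gt(ec_eo$mean_difference, 0)
})
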