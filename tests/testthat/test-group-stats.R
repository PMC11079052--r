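# fixed samples used for the frozen-oracle comparisons
gs_a <- c(1.2, 2.3, 3.1, 4.8, 2.2)
gs_b <- c(2.1, 3.9, 4.4, 6.2, 5.0, 3.3)
gs_c <- c(5.5, 6.1, 7.2, 8.9, 6.6, 7.0, 5.9)

test_that("welch_t matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  res <- welch_t(x, y)
  # independent formula oracle
  vx <- var(x) / 5; vy <- var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 4)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)

  same <- c(1.5, 2.5, 3.5)
  ident <- welch_t(same, same)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(2, 2, 2), c(2, 2, 2)), "zero pooled variance")
})

test_that("welch_anova reproduces the frozen reference values", {
  res <- welch_anova(list(a = gs_a, b = gs_b, c = gs_c))
  # frozen from an independent reference implementation
  expect_equal(res$f_star, 15.4908580593, tolerance = 1e-8)
  expect_equal(res$df2, 9.0795470744, tolerance = 1e-8)
  expect_equal(res$p, 0.0011840977, tolerance = 1e-6)
  expect_identical(res$df1, 2)
  expect_identical(res$group_summaries$n, c(5L, 6L, 7L))
})

test_that("groups shifted to a common mean give F* = 0 and p = 1", {
  base <- c(-1, 0, 1)
  res <- welch_anova(list(a = base + 5, b = 2 * base + 5, c = 3 * base + 5))
  expect_equal(res$f_star, 0)
  expect_equal(res$p, 1)
  expect_error(welch_anova(list(a = c(1, 1), b = c(1, 2))), "zero variance")
})

test_that("games_howell reproduces the frozen reference and the q = t*sqrt(2) identity", {
  gh <- games_howell(list(a = gs_a, b = gs_b, c = gs_c))
  expect_equal(gh$p_adj, c(0.2525256366, 0.0017182234, 0.0127349745),
               tolerance = 1e-6)
  expect_equal(gh$diff, c(-1.43, -4.0228571429, -2.5928571429),
               tolerance = 1e-9)
  wt <- welch_t(gs_a, gs_b)
  expect_equal(gh$q[1], abs(wt$t) * sqrt(2), tolerance = 1e-10)

  same <- games_howell(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(same$p_adj, 1)
})

test_that("the two-group consistency chain holds", {
  x <- c(3.2, 4.1, 5.6, 2.9, 4.4, 5.0)
  y <- c(6.1, 7.3, 5.9, 8.2, 7.7)
  wt <- welch_t(x, y)
  wa <- welch_anova(list(x = x, y = y))
  gh <- games_howell(list(x = x, y = y))
  expect_equal(wa$p, wt$p, tolerance = 1e-10)
  expect_equal(wa$f_star, wt$t^2, tolerance = 1e-10)
  expect_equal(gh$p_adj, wt$p, tolerance = 1e-6)
})

test_that("location shifts leave all statistics unchanged; scaling preserves p", {
  shift <- 13.7; scale <- 4.2
  wt0 <- welch_t(gs_a, gs_b)
  wt1 <- welch_t(gs_a + shift, gs_b + shift)
  expect_equal(wt1$t, wt0$t, tolerance = 1e-12)
  expect_equal(wt1$p, wt0$p, tolerance = 1e-12)
  wt2 <- welch_t(gs_a * scale, gs_b * scale)
  expect_equal(wt2$p, wt0$p, tolerance = 1e-12)

  wa0 <- welch_anova(list(gs_a, gs_b, gs_c))
  wa1 <- welch_anova(list(gs_a + shift, gs_b + shift, gs_c + shift))
  expect_equal(wa1$f_star, wa0$f_star, tolerance = 1e-12)
  gh0 <- games_howell(list(gs_a, gs_b, gs_c))
  gh1 <- games_howell(list(gs_a * scale, gs_b * scale, gs_c * scale))
  expect_equal(gh1$p_adj, gh0$p_adj, tolerance = 1e-10)
})

test_that("Tukey fences flag strictly outside points with interpolated quartiles", {
  fl <- tukey_outliers(c(1, 2, 3, 4, 100))
  expect_identical(fl$flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hand-computed fences: q1 = 2, q3 = 4, iqr = 2 -> [-1, 7]
  expect_equal(unname(fl$fences), c(-1, 7))

  none <- tukey_outliers(rep(5, 6))
  expect_false(any(none$flags))

  # a value exactly on the fence is not an outlier (strict inequality)
  on_fence <- tukey_outliers(c(1, 1, 3, 3, 6))   # fences [-2, 6]
  expect_false(any(on_fence$flags))
  past_fence <- tukey_outliers(c(1, 1, 3, 3, 6.1))
  expect_identical(sum(past_fence$flags), 1L)
  expect_error(tukey_outliers(c(1, 2, 3)), "at least 4")
})

test_that("removing outliers and re-flagging never readmits removed points", {
  for (seed in 1:6) {
    vals <- withr::with_seed(seed, c(rnorm(30), rnorm(3, 0, 12)))
    fl <- tukey_outliers(vals)
    if (sum(fl$flags) == 0 || sum(!fl$flags) < 4) next
    inner <- vals[!fl$flags]
    fl2 <- tukey_outliers(inner)
    removed <- vals[fl$flags]
    expect_true(all(removed < fl2$fences[1] | removed > fl2$fences[2]))
  }
})

test_that("box summaries follow the whisker convention", {
  vals <- c(1, 2, 3, 4, 5, 30)
  bs <- box_stats(vals)
  fl <- tukey_outliers(vals)
  expect_equal(bs$whisker_high, max(vals[!fl$flags]))
  expect_equal(bs$outliers, 30)
  expect_equal(bs$median, median(vals))
})
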