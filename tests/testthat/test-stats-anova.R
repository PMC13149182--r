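test_that("Levene: equal spreads give statistic 0; constant data p = 1", {
  g1 <- c(1, 2, 3, 4)
  expect_equal(levene_test(list(g1, g1 + 10))$statistic, 0)
  out <- levene_test(list(rep(2, 5), rep(7, 4)))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("Levene detects a 9-fold variance ratio (Monte Carlo power)", {
  set.seed(101)
  reject <- replicate(100, {
    levene_test(list(rnorm(200, 0, 1), rnorm(200, 0, 3)))$p_value < 0.01
  })
  expect_gte(mean(reject), 0.95)
})

test_that("Levene null calibration: permutation p-values are uniform", {
  set.seed(202)
  x <- rnorm(90)
  g <- rep(1:3, each = 30)
  pvals <- replicate(1000, {
    gp <- sample(g)
    levene_test(split(x, gp))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("identical groups give F = 0; summary and raw forms agree with aov", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(anova_oneway(g)$f_stat, 0)

  set.seed(33)
  groups <- random_group_data()
  a <- anova_oneway(groups)
  # oracle: base-R aov on the same data
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  or <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(a$f_stat, or[["F value"]][1], tolerance = 1e-10)
  expect_equal(a$p_value, or[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(a$df_between, length(groups) - 1L)
  expect_equal(a$df_within, sum(lengths(groups)) - length(groups))
})

test_that("summary-form F equals raw-form F to 1e-10 relative", {
  set.seed(44)
  for (i in 1:25) {
    groups <- random_group_data(k = sample(2:5, 1))
    a_raw <- anova_oneway(groups, lsd = FALSE)
    a_sum <- anova_from_summary(summarize_groups(groups), lsd = FALSE)
    expect_equal(a_sum$f_stat, a_raw$f_stat, tolerance = 1e-10)
    expect_equal(a_sum$p_value, a_raw$p_value, tolerance = 1e-10)
  }
})

test_that("summary replay of a printed table row gives the known F", {
  a <- anova_from_summary(data.frame(n = c(59, 58, 52),
                                     mean = c(416.75, 365.61, 202.91),
                                     sd = c(217.28, 221.03, 159.19)))
  expect_equal(a$f_stat, 16.50785, tolerance = 1e-5)  # frozen from the formula
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 166L)
  expect_lt(a$p_value, 0.001)
  expect_equal(nrow(a$lsd), 3)   # omnibus significant -> LSD runs
})

test_that("two identical summaries give F = 0; zero SD flags infinite F", {
  s <- data.frame(n = c(10, 10), mean = c(5, 5), sd = c(2, 2))
  expect_equal(anova_from_summary(s)$f_stat, 0)
  s2 <- data.frame(n = c(10, 10), mean = c(5, 6), sd = c(0, 0))
  out <- anova_from_summary(s2)
  expect_true(is.infinite(out$f_stat))
  expect_true("infinite_f" %in% out$flags)
})

test_that("LSD pairwise p-values match pooled-variance pairwise t tests", {
  set.seed(55)
  groups <- list(a = rnorm(20, 0), b = rnorm(25, 1.2), c = rnorm(18, 0.4))
  a <- anova_oneway(groups)
  or <- stats::pairwise.t.test(unlist(groups),
                               rep(names(groups), lengths(groups)),
                               p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(sort(a$lsd$p), sort(as.vector(or$p.value[!is.na(or$p.value)])),
               tolerance = 1e-10)
  # LSD gated on a non-significant omnibus
  set.seed(56)
  null_groups <- list(rnorm(20), rnorm(20), rnorm(20))
  a0 <- anova_oneway(null_groups)
  if (a0$p_value >= 0.05) expect_null(a0$lsd)
})

test_that("group preconditions are enforced", {
  expect_error(anova_oneway(list(c(1, 2))))              # one group
  expect_error(anova_oneway(list(c(1, 2), 3)))           # n < 2
  expect_error(anova_from_summary(data.frame(n = 1, mean = 0, sd = 1)))
})
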