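test_that("perfectly separated classes: AUC 1, sens and spec 100%", {
  r <- roc_youden(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_gte(r$cutoff, 2)
  expect_lt(r$cutoff, 3)
})

test_that("label-independent scores give AUC near 0.5", {
  set.seed(9)
  s <- rnorm(2000)
  lab <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(auc_mw(s, lab, "lower") - 0.5), 0.05)
})

test_that("Mann-Whitney AUC equals trapezoidal ROC integration to 1e-12", {
  set.seed(10)
  for (i in 1:30) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    # discretized scores force ties
    s <- round(c(rnorm(n1, 0.8), rnorm(n0)), sample(0:2, 1))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    ori <- sample(c("lower", "higher"), 1)
    expect_equal(auc_mw(s, lab, ori), auc_trapezoid(s, lab, ori),
                 tolerance = 1e-12)
  }
})

test_that("reversing orientation complements the AUC and swaps the rule", {
  set.seed(11)
  s <- rnorm(120)
  lab <- rep(c(TRUE, FALSE), 60)
  expect_equal(auc_mw(s, lab, "lower") + auc_mw(s, lab, "higher"), 1,
               tolerance = 1e-12)
  # negating scores under the opposite orientation is an exact identity
  rl <- roc_youden(s, lab, "lower")
  rh <- roc_youden(-s, lab, "higher")
  expect_equal(rl$auc, rh$auc, tolerance = 1e-12)
  expect_equal(rl$cutoff, -rh$cutoff, tolerance = 1e-12)
  expect_equal(rl$sensitivity, rh$sensitivity)
  expect_equal(rl$specificity, rh$specificity)
})

test_that("Youden cutoff maximizes sensitivity + specificity - 1", {
  set.seed(12)
  s <- c(rnorm(50, 1.2, 0.6), rnorm(70, 1.9, 0.6))
  lab <- rep(c(TRUE, FALSE), c(50, 70))
  r <- roc_youden(s, lab, "lower")
  # exhaustive-threshold oracle
  youden_at <- vapply(sort(unique(s)), function(c0)
    mean(s[lab] <= c0) + mean(s[!lab] > c0) - 1, 0)
  expect_equal(r$youden, max(youden_at), tolerance = 1e-12)
  expect_equal(r$sensitivity / 100 + r$specificity / 100 - 1, r$youden,
               tolerance = 1e-12)
})

test_that("single-class input errors", {
  expect_error(roc_youden(1:5, rep(TRUE, 5), "lower"), "non-empty")
  expect_error(auc_mw(1:5, rep(FALSE, 5), "lower"))
})

test_that("DeLong self-comparison: Z = 0, p = 1", {
  set.seed(13)
  s <- rnorm(60)
  lab <- rep(c(TRUE, FALSE), 30)
  d <- delong_test(s, s, lab, "lower")
  expect_equal(d$z_stat, 0)
  expect_equal(d$p_value, 1)
})

test_that("DeLong variance is non-negative and Z sign follows AUC ordering", {
  set.seed(14)
  for (i in 1:20) {
    lab <- rep(c(TRUE, FALSE), c(30, 40))
    a <- c(rnorm(30, -0.8), rnorm(40))   # informative, lower = disease
    b <- rnorm(70)                        # noise
    d <- delong_test(a, b, lab, "lower")
    expect_gte(d$var_diff, 0)
    if (d$z_stat != 0)
      expect_equal(sign(d$z_stat), sign(d$auc_a - d$auc_b))
  }
})

test_that("DeLong single-AUC variance agrees with bootstrap within 15%", {
  set.seed(15)
  n1 <- 60; n0 <- 80
  s <- c(rnorm(n1, -0.7), rnorm(n0))
  lab <- rep(c(TRUE, FALSE), c(n1, n0))
  v_delong <- auc_variance(s, lab, "lower")
  boots <- replicate(2000, {
    i1 <- sample(n1, replace = TRUE)
    i0 <- sample(n0, replace = TRUE)
    auc_mw(c(s[lab][i1], s[!lab][i0]),
           rep(c(TRUE, FALSE), c(n1, n0)), "lower")
  })
  expect_lt(abs(v_delong - var(boots)) / var(boots), 0.15)
})

test_that("binormal mixture AUC closed form", {
  expect_equal(binormal_auc(0, 1, 0, 1), 0.5)
  # mean gap equal to the RMS of the two SDs: Phi(1)
  expect_equal(binormal_auc(0, 1, sqrt(2), 1), pnorm(1), tolerance = 1e-12)
  # degenerate zero-variance components resolve as a step function
  expect_equal(binormal_auc(0, 0, c(1, -1, 0), c(0, 0, 0), c(1, 1, 2)), 0.5)
  # Monte Carlo check of the mixture form
  set.seed(16)
  m_nd <- c(1.85, 1.75); s_nd <- c(0.70, 0.61); n_nd <- c(59, 58)
  closed <- binormal_auc(1.19, 0.63, m_nd, s_nd, n_nd)
  mc <- mean(replicate(300, {
    d <- rnorm(200, 1.19, 0.63)
    nd <- c(rnorm(200 * n_nd[1] / sum(n_nd) * 2, m_nd[1], s_nd[1]),
            rnorm(200 * n_nd[2] / sum(n_nd) * 2, m_nd[2], s_nd[2]))
    auc_mw(c(d, nd), rep(c(TRUE, FALSE), c(length(d), length(nd))), "lower")
  }))
  expect_lt(abs(closed - mc), 0.01)
})
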