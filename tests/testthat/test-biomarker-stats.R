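test_that("correlation: Pearson/Spearman values, p, and contracts", {
  # strictly monotone nonlinear map: Spearman r = 1
  x <- 1:10
  expect_equal(correlate(x, exp(x), method = "spearman")$r, 1)
  # Spearman equals Pearson exactly on tie-free integer ranks
  set.seed(121)
  a <- sample(20)
  b <- sample(20)
  expect_equal(correlate(a, b, method = "spearman")$r,
               correlate(a, b, method = "pearson")$r, tolerance = 1e-12)
  # p via the t transform on n - 2 df (matches cor.test for Pearson)
  u <- rnorm(15); v <- rnorm(15)
  got <- correlate(u, v)
  ref <- cor.test(u, v)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate(1:4, 1:5), "lengths differ")
  expect_error(correlate(1:2, 2:3), "n >= 3")
})

test_that("partial correlation: recursion equals residual regression", {
  # independent control leaves r unchanged
  set.seed(131)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  z <- rnorm(200)  # independent of both
  r_plain <- correlate(x, y)$r
  # construct exact zero correlations via residuals for the closed-form case
  # first-order closed form on specified marginals: all r = 0.5 -> 1/3
  r_xy <- r_xz <- r_yz <- 0.5
  expect_equal((r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               1 / 3)

  # recursion and residual-correlation formulations agree to 1e-10 on
  # random data for all orders up to 3
  for (k in 1:3) {
    zz <- matrix(rnorm(200 * k), ncol = k)
    got <- partial_correlation(x, y, zz)
    expect_equal(got$r, oracle_partial_resid(x, y, zz), tolerance = 1e-10)
    # p consistent with the t transform on n - 2 - k df
    tt <- got$r * sqrt((200 - 2 - k) / (1 - got$r^2))
    expect_equal(got$p, 2 * pt(-abs(tt), 200 - 2 - k), tolerance = 1e-12)
  }
  # independent control: partial r close to the plain r (population equal)
  expect_equal(partial_correlation(x, y, z)$r, r_plain, tolerance = 0.05)
  # degenerate control: x used as its own control
  expect_error(partial_correlation(x, y, x), "degenerate")
  expect_error(partial_correlation(x[1:4], y[1:4], cbind(z[1:4], z[1:4] * 2)),
               "n >= ")
})

test_that("ANOVA with Dunnett: F = t^2 for two groups, separation limit", {
  set.seed(141)
  g1 <- rnorm(8); g2 <- rnorm(8, 1)
  res <- anova_dunnett(c(g1, g2), rep(c("ctrl", "trt"), each = 8),
                       control = "ctrl")
  tt <- t.test(g2, g1, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_overall, tt$p.value, tolerance = 1e-10)
  # single comparison: Dunnett adjustment reduces to the plain two-sided p
  expect_equal(res$comparisons$p_adjusted, tt$p.value, tolerance = 1e-3)

  # well-separated mean with tiny variance: overall and Dunnett p collapse
  y <- c(rnorm(6, 0, 1e-3), rnorm(6, 0, 1e-3), rnorm(6, 10, 1e-3))
  g <- rep(c("ctrl", "a", "b"), each = 6)
  sep <- anova_dunnett(y, g, control = "ctrl")
  expect_lt(sep$p_overall, 1e-12)
  expect_lt(sep$comparisons$p_adjusted[sep$comparisons$stratum == "b"], 1e-12)
  expect_gt(sep$comparisons$p_adjusted[sep$comparisons$stratum == "a"], 0.05)

  # agreement with multcomp's independent Dunnett implementation
  y2 <- rnorm(30)
  g2f <- factor(rep(c("ctrl", "a", "b"), each = 10), c("ctrl", "a", "b"))
  ours <- anova_dunnett(y2, g2f, control = "ctrl")
  mc <- summary(multcomp::glht(stats::aov(y2 ~ g2f),
                               linfct = multcomp::mcp(g2f = "Dunnett")))
  expect_equal(sort(ours$comparisons$p_adjusted),
               sort(as.numeric(mc$test$pvalues)), tolerance = 5e-3)

  expect_error(anova_dunnett(rep(1, 6), rep(c("a", "b"), 3)), "identical")
  expect_error(anova_dunnett(1:4, c("a", "a", "a", "b")), "n >= 2")
})

test_that("Dunnett family-wise error stays in band under the null", {
  set.seed(151)
  n_rep <- 1500
  any_sig <- logical(n_rep)
  g <- rep(c("ctrl", "a", "b"), each = 6)
  for (i in seq_len(n_rep)) {
    y <- rnorm(18)
    res <- anova_dunnett(y, g, control = "ctrl")
    any_sig[i] <- any(res$comparisons$p_adjusted < 0.05)
  }
  fwer <- mean(any_sig)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fwer, 0.05 + 3 * se)
})

test_that("chi-square rate test matches the O-E arithmetic", {
  # identical rates: statistic 0, p = 1
  same <- chi_square_rate(c(10, 20), c(50, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # [[10,90],[30,70]]: direct sum((O-E)^2/E) with margins 40/160
  res <- chi_square_rate(c(10, 30), c(100, 100))
  O <- c(10, 30, 90, 70)
  E <- c(20, 20, 80, 80)
  expect_equal(res$statistic, sum((O - E)^2 / E))
  expect_equal(res$df, 1)
  expect_error(chi_square_rate(5, 10), ">= 2 conditions")
  expect_error(chi_square_rate(c(0, 0), c(10, 10)), "expected cell")
})

test_that("2^-ddCt relative quantification arithmetic", {
  expect_equal(relative_quantification(20, 18, 20, 18), 1)  # ddCt = 0
  expect_equal(relative_quantification(19, 18, 20, 18), 2)  # ddCt = -1
  # sample dCt = 2, calibrator dCt = 5: fold = 2^3 = 8
  expect_equal(relative_quantification(22, 20, 25, 20), 8)
  expect_error(relative_quantification(NA, 1, 1, 1), "finite")
})

test_that("exposure stratification uses lower-closed upper-open intervals", {
  s <- stratify_exposure(c(0.5, 2.0, 4.9, 5.0, 80), cuts = c(0, 2, 5))
  expect_equal(as.character(s), c("[0,2)", "[2,5)", "[2,5)", ">=5", ">=5"))
  # boundary value 2.0 goes up into the middle stratum
  expect_equal(as.character(s[2]), "[2,5)")
  # all values below 2: single occupied stratum
  low <- stratify_exposure(runif(50, 0.1, 1.9), cuts = c(0, 2, 5))
  expect_equal(sum(table(low) > 0), 1L)
  expect_error(stratify_exposure(c(-1, 3), cuts = c(0, 2, 5)), "below")
  expect_error(stratify_exposure(1, cuts = c(2, 2, 5)), "increasing")

  # planted stratum proportions recovered from the generated cohort
  co <- generate_exposure_cohort(std_config(), n = 20000)
  # lognormal(median 1.61, sigma 1): P(X < 2) = pnorm(log(2/1.61))
  expected <- diff(c(0, pnorm(log(2 / 1.61)), pnorm(log(5 / 1.61)), 1))
  got <- as.numeric(table(co$UCd_stratum)) / nrow(co)
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("cohort correlations converge to the configured targets", {
  co <- generate_exposure_cohort(std_config(seed = 3), n = 10000)
  vars <- c("UCd", "BCd", "B2MG", "lnc_expr")
  emp <- cor(co[, vars])
  # full-matrix bound frozen from a Monte-Carlo sampling-error pass: the
  # heaviest-tailed pairs (both margins sigma = 1) have r-hat SE ~ 0.02 at
  # n = 10^4, so 4 SE = 0.08 bounds the worst entry
  expect_lt(max(abs(emp - default_cohort_target_r())), 0.08)
  # the reported worker correlation: r(BCd, expression) targets 0.610;
  # its r-hat SE is ~ 0.0125, so 0.03 is a ~2.4 SE Monte-Carlo bound
  expect_lt(abs(correlate(co$BCd, co$lnc_expr)$r - 0.610), 0.03)
})
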