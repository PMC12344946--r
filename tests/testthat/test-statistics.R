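# Normality-gated comparisons, BH, effect sizes, chi-square, ICC.

test_that("normal, equal-variance groups take the pooled t path", {
  r <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_identical(r$test, "t")
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_true(r$normal_gate)
  expect_true(r$equal_var_gate)
  expect_match(r$summary_a, "±")
})

test_that("heavy-tailed data take the Mann-Whitney path and ties give p = 1", {
  set.seed(8)
  a <- exp(rnorm(30, 0, 1.5)); a <- c(a, 50, 80)  # strongly lognormal
  r <- compare_groups(a, a)
  expect_identical(r$test, "mann_whitney")
  expect_equal(r$p_value, 1)
  expect_match(r$summary_a, "\\(")
  b <- exp(rnorm(30, 0.8, 1.5))
  r2 <- compare_groups(a, b)
  expect_identical(r2$test, "mann_whitney")
})

test_that("comparison is symmetric under group swap", {
  set.seed(13)
  a <- rnorm(20, 0, 1); b <- rnorm(25, 0.7, 1)
  r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  if (r1$test %in% c("t", "welch_t")) {
    expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  } else {
    expect_equal(r1$statistic, 20 * 25 - r2$statistic)
  }
  expect_equal(r1$cohens_d, -r2$cohens_d, tolerance = 1e-12)
  # U-path symmetry too
  al <- exp(a); bl <- exp(b + rnorm(25, 0, 2))
  u1 <- compare_groups(al, bl); u2 <- compare_groups(bl, al)
  if (u1$test == "mann_whitney") {
    expect_equal(u1$statistic, 20 * 25 - u2$statistic)
    expect_equal(u1$p_value, u2$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate comparisons error", {
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(rep(0.5, 6)), rep(0.5, 6))
  expect_equal(adjust_bh(0.037), 0.037)
  p <- c(0.4, 0.001, 0.02)
  expect_true(all(adjust_bh(p) >= p))
  expect_equal(order(adjust_bh(p)), order(p))  # order-preserving
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d matches the hand computation and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(2)
  a <- rnorm(15); b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b), cohens_d(3 + 2 * a, 3 + 2 * b),
               tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 4), rep(1, 4)), "pooled SD")
})

test_that("d sign convention reproduces the published table directions", {
  # feed summaries-consistent synthetic groups; check d sign against the
  # published effect direction wherever the printed |d| is decisive
  summ <- reported_parameter_summaries()
  set.seed(17)
  draw <- function(group, p, n = 4000) {
    r <- summ[summ$group == group & summ$parameter == p, ]
    rnorm(n, r$location, r$scale)
  }
  reported_sign <- c(Mono_ADC = -1, IVIM_D = -1, IVIM_Dstar = -1, IVIM_f = 1,
                     SEM_alpha = -1, SEM_DDC = -1, CTRW_alpha = -1,
                     CTRW_beta = 1, CTRW_Dm = -1)  # IDH rows
  for (p in names(reported_sign)) {
    d <- cohens_d(draw("idh_wild", p),
                  c(draw("noncodeleted", p, 1200), draw("codeleted", p, 2800)))
    expect_identical(sign(d), reported_sign[[p]], label = paste("IDH", p))
  }
  reported_sign_q <- c(Mono_ADC = 1, IVIM_D = 1, SEM_DDC = 1,
                       CTRW_alpha = 1, CTRW_beta = -1, CTRW_Dm = 1)
  for (p in names(reported_sign_q)) {
    d <- cohens_d(draw("noncodeleted", p), draw("codeleted", p))
    expect_identical(sign(d), reported_sign_q[[p]], label = paste("1p19q", p))
  }
})

test_that("chi-square handles the published 2x2 and a 2x3 oracle", {
  # gender x IDH: all expected counts >= 10, plain Pearson, not significant
  tab <- rbind(c(28, 24), c(26, 17))
  r <- chi_square_categorical(tab)
  expect_false(r$correction)
  brute <- sum((tab - r$expected)^2 / r$expected)
  expect_equal(r$statistic, brute, tolerance = 1e-12)
  expect_gt(r$p_value, 0.05)
  # perfectly proportional table
  r0 <- chi_square_categorical(rbind(c(10, 20), c(30, 60)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # 2x3 location-style table equals the brute-force statistic
  tab3 <- rbind(c(18, 6, 28), c(31, 1, 12))
  r3 <- chi_square_categorical(tab3)
  expect_equal(r3$statistic, sum((tab3 - r3$expected)^2 / r3$expected),
               tolerance = 1e-12)
  # small-expected 2x2 gets Yates
  r4 <- chi_square_categorical(rbind(c(4, 48), c(0, 43)))
  expect_true(r4$correction)
  expect_error(chi_square_categorical(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chi_square_categorical(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("ICC(2,1) has its defining properties", {
  set.seed(4)
  x <- rnorm(12, 10, 3)
  expect_equal(icc_two_way_random(cbind(x, x))$icc, 1, tolerance = 1e-9)
  r_off <- icc_two_way_random(cbind(x, x + 2))
  expect_lt(r_off$icc, 1)  # absolute agreement penalizes a constant offset
  expect_gt(r_off$icc, 0)
  expect_true(r_off$ci_lo <= r_off$icc && r_off$icc <= r_off$ci_hi)
  expect_error(icc_two_way_random(matrix(1, 6, 2)), "constant")
  expect_error(icc_two_way_random(matrix(rnorm(8), 4, 2)), ">= 5 subjects")
})

test_that("ICC(2,1) recovers a known variance ratio", {
  # subjects sigma^2 = 9, error sigma^2 = 1 -> ICC ~ 0.9
  set.seed(30)
  n <- 100
  subj <- rnorm(n, 0, 3)
  ratings <- cbind(subj + rnorm(n), subj + rnorm(n))
  r <- icc_two_way_random(ratings)
  expect_equal(r$icc, 0.9, tolerance = 0.05)
})

test_that("the 18-hypothesis table is jointly BH-adjusted", {
  set.seed(44)
  coh <- values_cohort(list(wild = rnorm(20, 1.0, 0.1),
                            noncodel = rnorm(8, 1.3, 0.1),
                            codel = rnorm(12, 1.15, 0.1)))
  tab <- genotype_comparison_table(coh)
  expect_identical(nrow(tab), 18L)
  expect_true(all(tab$p_bh >= tab$p_raw))
  expect_equal(tab$p_bh, adjust_bh(tab$p_raw))
  expect_setequal(unique(tab$question), c("IDH", "1p19q"))
})
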