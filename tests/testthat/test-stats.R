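test_that("TANOVA: null cases, exact enumeration, and invariances", {
  set.seed(1)
  a <- matrix(rnorm(6 * 16), 6)
  tv <- tanova(a, a)
  expect_equal(tv$statistic, 0)
  expect_equal(tv$p, 1)
  # maximal separation with a shared topography: p = 2 / 2^5
  base <- rnorm(16); base <- base - mean(base)
  am <- t(sapply(1:5, function(i) base + 0.1 * rnorm(16)))
  expect_equal(tanova(am, -am)$p, 1 / 16)
  # exact and Monte-Carlo modes agree within sampling error
  b <- a + matrix(rnorm(6 * 16, sd = 0.8), 6)
  pe <- tanova(a, b, exact = TRUE)$p
  pm <- tanova(a, b, exact = FALSE, n_perm = 10000, seed = 2)$p
  expect_lt(abs(pe - pm), 2 / sqrt(10000) + 0.01)
  # invariant under a global channel permutation
  perm <- sample(16)
  expect_equal(tanova(a[, perm], b[, perm], exact = TRUE)$p, pe)
  expect_error(tanova(a, b[1:3, ]), "paired")
})

test_that("TANOVA Monte-Carlo type-I error is calibrated at alpha = 0.05", {
  set.seed(3)
  rej <- replicate(300, {
    a <- matrix(rnorm(10 * 16), 10)
    b <- matrix(rnorm(10 * 16), 10)
    tanova(a, b, n_perm = 199, exact = FALSE)$p <= 0.05
  })
  ci <- 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(rej) - 0.05), ci + 1e-12)
})

test_that("repeated-measures ANOVA matches independent oracles", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    df <- expand.grid(subject = seq_len(n), class = factor(1:4),
                      condition = factor(c("neutral", "fear")))
    df$time_coverage <- rnorm(nrow(df))
    an <- rm_anova(df, "time_coverage")
    # brute-force sums-of-squares oracle
    o <- rm_anova_oracle(df, "time_coverage")
    expect_equal(an$F, unname(o), tolerance = 1e-9)
    # aov Error-stratum cross-check
    s <- summary(stats::aov(time_coverage ~ class * condition +
                              Error(factor(subject) / (class * condition)),
                            data = df))
    expect_equal(an$F[3],
                 s[["Error: factor(subject):class:condition"]][[1]]$F[1],
                 tolerance = 1e-9)
  }
  # a pure one-class condition shift produces a significant interaction
  df <- expand.grid(subject = 1:8, class = factor(1:4),
                    condition = factor(c("neutral", "fear")))
  set.seed(5)
  df$y <- rnorm(nrow(df), sd = 0.01)
  df$y[df$class == "3" & df$condition == "fear"] <-
    df$y[df$class == "3" & df$condition == "fear"] + 1
  an <- rm_anova(df, "y")
  expect_gt(an$F[3], stats::qf(0.95, an$df[3], an$df_error[3]))
  expect_error(rm_anova(df[-1, ], "y"), "complete")
})

test_that("interaction p values are uniform under the null", {
  set.seed(6)
  ps <- replicate(200, {
    df <- expand.grid(subject = 1:6, class = factor(1:4),
                      condition = factor(1:2))
    df$y <- rnorm(nrow(df))
    rm_anova(df, "y")$p[3]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("paired t handles identity, degeneracy, and matches t.test", {
  x <- rnorm(10)
  t0 <- paired_t(x, x)
  expect_equal(c(t0$t, t0$p, t0$d), c(0, 1, 0))
  td <- paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(td$degenerate)
  expect_true(is.na(td$t))
  set.seed(7)
  y <- rnorm(10)
  tt <- paired_t(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$d, mean(x - y) / sqrt((var(x) + var(y)) / 2),
               tolerance = 1e-12)
  expect_error(paired_t(1:2, 2:3), "at least 3")
  # type-I calibration
  set.seed(8)
  rej <- replicate(2000, paired_t(rnorm(12), rnorm(12))$p <= 0.05)
  expect_lt(abs(mean(rej) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 2000) + 1e-12)
})

test_that("paired contrasts apply the Bonferroni family threshold", {
  set.seed(9)
  tab <- expand.grid(subject = 1:10, condition = c("neutral", "fear"),
                     class = 1:4)
  tab$mean_duration <- rnorm(nrow(tab), 75, 5)
  tab$time_coverage <- rnorm(nrow(tab), 0.25, 0.02)
  out <- paired_contrasts(tab, alpha = 0.05)
  expect_equal(nrow(out), 8)
  expect_equal(unique(out$threshold), 0.05 / 8)
  out2 <- paired_contrasts(tab, alpha_family = 0.003)
  expect_equal(unique(out2$threshold), 0.003)
})

test_that("BH step-up reproduces enumerated decisions and dominates Bonferroni", {
  # family (0.01, 0.02, 0.03, 0.04) at alpha = 0.05: all rejected by step-up
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(stats::p.adjust(p, "BH") <= 0.05))
  set.seed(10)
  tr <- rnorm(20)
  prm <- matrix(rnorm(20 * 6), 20,
                dimnames = list(NULL, paste0("v", 1:6)))
  prm[, 1] <- tr + rnorm(20, sd = 0.1)
  res <- pearson_with_fdr(tr, prm, alpha = 0.05)
  bonf <- res$p <= 0.05 / nrow(res)
  expect_true(all(sum(res$reject_fdr) >= sum(bonf)))
  expect_true(res$reject_fdr[1])
  # perfect linear relation
  r1 <- pearson_with_fdr(1:10, matrix(2 * (1:10) + 3, 10))
  expect_equal(r1$r, 1)
  expect_error(pearson_with_fdr(rep(1, 10), matrix(rnorm(10), 10)),
               "zero-variance")
})

test_that("trait slopes in simulated cohorts are recovered with the right sign", {
  # class-D coverage is generated with a negative trait slope
  set.seed(11)
  hits <- replicate(40, {
    spec <- cohort_spec(n_subjects = 24, n_epochs_per_condition = 1,
                        epoch_s = 1, seed = sample.int(1e6, 1))
    coh <- simulate_cohort(spec, std_gt)
    tn <- coh$truth[coh$truth$condition == "neutral" & coh$truth$class == 4, ]
    cor(coh$trait$trait, tn$time_coverage[order(tn$subject)]) < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("neuroticism scoring and odd-even reliability behave as specified", {
  expect_equal(bfi_neuroticism_score(rep(1, 8)), 8L)
  expect_equal(bfi_neuroticism_score(rep(5, 8)), 40L)
  expect_equal(bfi_neuroticism_score(rep(3, 8)), 24L)
  expect_equal(bfi_neuroticism_score(rep(1, 8), reverse_keys = c(2, 5)), 16L)
  expect_error(bfi_neuroticism_score(rep(6, 8)), "in \\[1, 5\\]")
  expect_error(bfi_neuroticism_score(rep(3, 7)), "8 items")
  m <- matrix(sample(1:5, 36 * 8, replace = TRUE), 36)
  expect_length(bfi_neuroticism_score(m), 36)
  # duplicated odd/even halves correlate perfectly
  half <- matrix(rnorm(12 * 4), 12)
  dup <- half[, rep(1:4, each = 2)]
  expect_equal(odd_even_reliability(dup), 1)
  set.seed(12)
  null_r <- replicate(50, odd_even_reliability(matrix(rnorm(36 * 8), 36)))
  expect_lt(max(abs(null_r)), 0.6)
  # one-factor items approach the Spearman-Brown expectation
  set.seed(13)
  f <- rnorm(500)
  items <- sapply(1:8, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(500))
  r_half <- odd_even_reliability(items)
  # corr of two 4-item sums under the one-factor model:
  # cov = (4 * 0.7)^2, var = (4 * 0.7)^2 + 4 * (1 - 0.7^2)
  rho_half <- (16 * 0.49) / (16 * 0.49 + 4 * 0.51)
  expect_equal(r_half, rho_half, tolerance = 0.08)
})
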