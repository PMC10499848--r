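# Exhaustive two-sided signed-rank p-value over all 2^n sign assignments
# of the absolute differences (no ties assumed).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_hi <- mean(v_all >= v_obs)
  p_lo <- mean(v_all <= v_obs)
  min(1, 2 * min(p_hi, p_lo))
}

test_that("identical paired samples are flagged degenerate", {
  x <- c(1, 2, 3, 4, 5)
  r <- gated_paired_compare(x, x)
  expect_true(r$degenerate)
  expect_false(r$significant)
  expect_true(is.na(r$p_value))
})

test_that("normal paired data route to the paired t-test", {
  withr::with_seed(100, {
    x <- rnorm(8, 1.5, 0.3)
    y <- rnorm(8, 0.2, 0.3)
    r <- gated_paired_compare(x, y)
    expect_equal(r$test_used, "paired-t")
    expect_gte(r$shapiro_p, 0.05)
    expect_true(r$significant)
    expect_equal(r$direction, "x")
    tt <- t.test(x, y, paired = TRUE)
    expect_equal(r$p_value, tt$p.value)
  })
})

test_that("non-normal differences route to the exact Wilcoxon signed-rank test", {
  found <- 0
  for (seed in 1:40) {
    d <- withr::with_seed(seed, rcauchy(9))
    x <- d + 1
    y <- rep(1, 9)
    if (shapiro.test(d)$p.value < 0.05) {
      r <- gated_paired_compare(x, y)
      expect_equal(r$test_used, "wilcoxon")
      expect_equal(r$p_value, exact_signed_rank_p(d), tolerance = 1e-12)
      found <- found + 1
    }
    if (found >= 5) break
  }
  expect_gte(found, 5)
})

test_that("the Wilcoxon branch matches the 2^n enumeration across n <= 10", {
  for (seed in 1:12) {
    n <- 5 + (seed %% 6)
    d <- withr::with_seed(seed + 500, rcauchy(n))
    wt <- suppressWarnings(wilcox.test(d, exact = TRUE))
    expect_equal(wt$p.value, exact_signed_rank_p(d), tolerance = 1e-12,
                 label = sprintf("seed %d n %d", seed, n))
  }
})

test_that("gate decisions are reproducible for identical input", {
  withr::with_seed(7, {
    x <- rexp(10)
    y <- rexp(10)
  })
  r1 <- gated_paired_compare(x, y)
  r2 <- gated_paired_compare(x, y)
  expect_identical(r1[c("test_used", "statistic", "p_value")],
                   r2[c("test_used", "statistic", "p_value")])
})

test_that("one-way ANOVA behaves like the classical decomposition", {
  withr::with_seed(11, {
    g <- lapply(1:3, function(i) rnorm(10, 0, 1))
    r <- oneway_anova(g)
    expect_equal(r$test_used, "anova")
    expect_gt(r$p_value, 0.01)
    # two-group ANOVA F equals the squared pooled t statistic
    a <- rnorm(12, 0); b <- rnorm(12, 0.8)
    r2 <- oneway_anova(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r2$p_value, tt$p.value, tolerance = 1e-10)
  })
  # identical groups with zero variance: no defined F
  expect_true(oneway_anova(list(c(1, 1), c(1, 1)))$degenerate)
  expect_error(oneway_anova(list(1:3)), "at least 2 groups")
})

test_that("identical group means with noise give a small F and large p", {
  withr::with_seed(12, {
    g <- lapply(1:3, function(i) 5 + rnorm(50, 0, 1))
    r <- oneway_anova(g)
    expect_lt(r$statistic, 3)
    expect_gt(r$p_value, 0.05)
  })
})
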