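test_that("all-zero differences give p = 1 with a degeneracy flag", {
  x <- c(1, 2, 3)
  w <- wilcoxon_signed_rank_exact(x, x)
  expect_true(w$all_zero)
  expect_equal(w$p_two_sided, 1)
  expect_equal(w$statistic_W, 0)
  expect_error(wilcoxon_signed_rank_exact(1:3, 1:4), "equal length")
})

test_that("three positive unit differences give W = 6 and exact p = 0.25", {
  w <- wilcoxon_signed_rank_exact(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w$statistic_W, 6)
  expect_equal(w$p_two_sided, 0.25)
  expect_identical(w$method, "exact_enumeration")
})

test_that("exact p equals the brute-force enumeration oracle bit-for-bit", {
  set.seed(7)
  for (k in 1:60) {
    n <- sample(2:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_signed_rank_exact(x, y)
    oracle <- wilcoxon_enumeration_oracle(x, y)
    expect_identical(got$statistic_W, oracle$W)
    expect_identical(got$p_two_sided, oracle$p)
    # and, for tie-free data, the stats package's exact test agrees
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ties are handled with mid-ranks, still matching enumeration", {
  set.seed(9)
  for (k in 1:25) {
    n <- sample(3:9, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (all(x == y)) next
    got <- wilcoxon_signed_rank_exact(x, y)
    oracle <- wilcoxon_enumeration_oracle(x, y)
    expect_identical(got$statistic_W, oracle$W)
    expect_identical(got$p_two_sided, oracle$p)
  }
})

test_that("the test statistic is symmetric in its arguments", {
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    a <- wilcoxon_signed_rank_exact(x, y)
    b <- wilcoxon_signed_rank_exact(y, x)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-14)
    expect_equal(a$statistic_W + b$statistic_W,
                 a$n_effective * (a$n_effective + 1) / 2)
  }
})

test_that("W stays within its combinatorial bounds and p in (0, 1]", {
  set.seed(13)
  for (k in 1:50) {
    n <- sample(1:14, 1)
    x <- rnorm(n); y <- rnorm(n)
    w <- wilcoxon_signed_rank_exact(x, y)
    expect_gte(w$statistic_W, 0)
    expect_lte(w$statistic_W, w$n_effective * (w$n_effective + 1) / 2)
    expect_gt(w$p_two_sided, 0)
    expect_lte(w$p_two_sided, 1)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  w <- wilcoxon_signed_rank_exact(x, y)
  expect_identical(w$method, "normal_approximation")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(w$p_two_sided, ref$p.value, tolerance = 1e-10)
  # exact_limit can force the exact path
  w2 <- wilcoxon_signed_rank_exact(x, y, exact_limit = 20)
  expect_identical(w2$method, "exact_enumeration")
})

test_that("zero differences are discarded (classical convention)", {
  x <- c(5, 3, 3, 8)
  y <- c(5, 1, 1, 2)
  w <- wilcoxon_signed_rank_exact(x, y)
  expect_equal(w$n_effective, 3)
  expect_equal(w$statistic_W, 6) # mid-ranks 1.5, 1.5, 3, all positive
})
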