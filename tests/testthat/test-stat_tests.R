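test_that("pooled t-test agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- rnorm(n1, runif(1, -1, 1)); y <- rnorm(n2)
    got <- t_test_upper(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE, alternative = "greater")
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
    expect_identical(got$reject, ref$p.value < 0.05)
  }
})

test_that("pooled t-test handles identical and degenerate samples", {
  x <- c(1, 2, 3)
  res <- t_test_upper(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.5)
  expect_false(res$reject)
  expect_error(t_test_upper(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("WMT agrees with the reference implementation, exact and approximate", {
  set.seed(22)
  for (i in 1:60) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)   # exact branch (<= 20 total)
    x <- rnorm(n1, runif(1, -1, 1)); y <- rnorm(n2)
    got <- wmt_upper(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater")
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  }
  for (i in 1:20) {                              # normal-approximation branch
    x <- rnorm(15); y <- rnorm(15, 0.3)
    got <- wmt_upper(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = FALSE, correct = TRUE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("WMT exact p follows from rank enumeration and rejection is strict", {
  # all 20 assignments of 3 ranks out of 6: only one gives the maximal
  # rank sum, so the one-sided p is 1/20 = 0.05, which must NOT reject
  res <- wmt_upper(c(4, 5, 6), c(1, 2, 3), alpha = 0.05)
  expect_equal(res$p.value, 0.05)
  expect_false(res$reject)
  same <- wmt_upper(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p.value, 0.5)
  expect_false(same$reject)
})

test_that("effect statistics use the averaged-variance pooled sd and are antisymmetric", {
  set.seed(23)
  for (i in 1:25) {
    x <- rnorm(8, 1); y <- rnorm(10)
    es <- effect_stats(x, y)
    expect_equal(es$pooled_sd, sqrt((var(x) + var(y)) / 2))
    expect_equal(es$cohens_d, es$effect_size / es$pooled_sd)
    rev <- effect_stats(y, x)
    expect_equal(rev$effect_size, -es$effect_size)
    expect_equal(rev$cohens_d, -es$cohens_d)
  }
  x <- c(1, 2, 3)
  expect_equal(effect_stats(x, x)$cohens_d, 0)
  expect_error(effect_stats(c(1, 1), c(1, 1)), "constant")
})

test_that("BH adjustment matches the step-up rule and is order-preserving", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(24)
  for (i in 1:20) {
    p <- runif(7)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p) && all(adj <= 1))
    perm <- sample(7)
    expect_equal(bh_adjust(p[perm]), adj[perm])  # values travel with inputs
  }
})

test_that("shifting one group upward never increases the upper-sided t p-value", {
  set.seed(25)
  for (i in 1:30) {
    x <- rnorm(6); y <- rnorm(8)
    p0 <- t_test_upper(x, y)$p.value
    p1 <- t_test_upper(x + runif(1, 0, 2), y)$p.value
    expect_lte(p1, p0)
  }
})

test_that("vectorised row p-values match the scalar tests", {
  set.seed(26)
  X <- matrix(rnorm(40 * 9, 0.5), 40, 9)
  Y <- matrix(rnorm(40 * 10), 40, 10)
  pt_rows <- npirep:::.t_p_rows(X, Y)
  pw_rows <- npirep:::.wmt_p_rows(X, Y)
  for (i in c(1, 7, 40)) {
    expect_equal(pt_rows[i], t_test_upper(X[i, ], Y[i, ])$p.value,
                 tolerance = 1e-12)
    expect_equal(pw_rows[i], wmt_upper(X[i, ], Y[i, ])$p.value,
                 tolerance = 1e-12)
  }
})
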