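test_that("spearman statistic is exact on monotone and antitone inputs", {
  expect_equal(unname(spearman_test(1:4, c(10, 20, 30, 40))$statistic), 1)
  expect_equal(unname(spearman_test(1:3, 3:1)$statistic), -1)
})

test_that("exact spearman p matches permutation enumeration and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearman_test(x, y)
  expect_equal(unname(r$statistic), 0.8)
  expect_equal(r$p.value, oracle_spearman_p(x, y, "two.sided"))
  expect_equal(r$p.value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(spearman_test(x, y, alt)$p.value,
                   oracle_spearman_p(x, y, alt))
    }
  }
})

test_that("a constant vector raises a classed undefined-result error", {
  expect_error(spearman_test(rep(2, 5), rnorm(5)),
               class = "kraswnt_undefined_error")
  expect_error(spearman_test(rnorm(5), rep(1, 5)),
               class = "kraswnt_undefined_error")
})

test_that("rank-sum exact p matches enumeration; textbook case is 1/10", {
  r <- rank_sum_test(c(3, 4, 5), c(1, 2), "greater", exact = TRUE)
  expect_equal(r$p.value, 0.1)
  set.seed(202)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    for (alt in c("two.sided", "greater", "less"))
      expect_equal(rank_sum_test(x, y, alt, exact = TRUE)$p.value,
                   oracle_rank_sum_p(x, y, alt))
    # ties via rounding
    xr <- round(x); yr <- round(y)
    expect_equal(rank_sum_test(xr, yr, "greater", exact = TRUE)$p.value,
                 oracle_rank_sum_p(xr, yr, "greater"))
  }
})

test_that("rank-sum symmetry: identical groups give p >= 0.5, tails swap", {
  x <- c(1.2, 3.4, 2.2)
  expect_gte(rank_sum_test(x, x, "greater")$p.value, 0.5)
  set.seed(303)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(rank_sum_test(x, y, "greater")$p.value,
                 rank_sum_test(y, x, "less")$p.value)
    expect_equal(rank_sum_test(x, y, "greater", exact = TRUE)$p.value,
                 rank_sum_test(y, x, "less", exact = TRUE)$p.value)
  }
})

test_that("signed-rank exact p matches sign enumeration; all-positive n=5 is 1/32", {
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5), 0, "greater")$p.value,
               1 / 32)
  set.seed(404)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n, sd = 2)
    for (alt in c("two.sided", "greater", "less"))
      expect_equal(signed_rank_test(x, 0, alt)$p.value,
                   oracle_signed_rank_p(x, 0, alt))
  }
})

test_that("signed-rank edge semantics: zeros removed, degenerate input errors", {
  expect_error(signed_rank_test(rep(1, 6), 1), "undefined")
  expect_warning(r <- signed_rank_test(c(0, 1, 2, 3, 4, 5), 0, "greater"),
                 "removed")
  expect_equal(r$p.value, 1 / 32)
  # symmetric sample: two-sided p is large
  x <- c(-3, -2, -1, 1, 2, 3)
  expect_gte(signed_rank_test(x, 0, "two.sided")$p.value, 0.5)
})

test_that("fisher 2x2 matches hypergeometric enumeration; diagonal case is 1/252", {
  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE), "greater")
  expect_equal(r$p.value, 1 / 252)
  bal <- fisher_exact_2x2(matrix(1, 2, 2), "greater")
  expect_equal(unname(bal$estimate), 1)
  expect_gte(bal$p.value, 0.5)
  set.seed(505)
  for (i in 1:30) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tab, alt)$p.value,
                   oracle_fisher_2x2(tab, alt))
    }
    expect_equal(fisher_exact_2x2(tab)$p.value,
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("fisher 2x2 odds-ratio conventions", {
  expect_equal(unname(fisher_exact_2x2(matrix(c(4, 1, 2, 3), 2,
                                              byrow = TRUE))$estimate), 6)
  expect_equal(unname(fisher_exact_2x2(matrix(c(4, 0, 2, 3), 2,
                                              byrow = TRUE))$estimate), Inf)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integers")
})

test_that("fisher r x c: 2x2 agrees with the 2x2 test; small tables match brute force", {
  tab <- matrix(c(5, 1, 2, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(tab)$p.value,
               fisher_exact_2x2(tab, "two.sided")$p.value)
  set.seed(606)
  for (i in 1:15) {
    tab <- matrix(sample(0:4, 6, replace = TRUE), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p.value, oracle_fisher_rxc(tab),
                 tolerance = 1e-10)
  }
})

test_that("fisher r x c: degenerate margins dropped, identical rows give p = 1", {
  expect_warning(r <- fisher_exact_rxc(matrix(c(3, 0, 2, 5, 0, 4), 2,
                                              byrow = TRUE)),
                 "zero")
  expect_true(r$p.value <= 1)
  same <- matrix(c(4, 3, 2, 4, 3, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(same)$p.value, 1)
})

test_that("fisher r x c Monte-Carlo mode: seeded, add-one corrected, near exact", {
  tab <- matrix(c(20, 5, 9, 4, 18, 10), 2, byrow = TRUE)  # total > 40
  r1 <- fisher_exact_rxc(tab, n_mc = 4000, seed = 7)
  r2 <- fisher_exact_rxc(tab, n_mc = 4000, seed = 7)
  expect_identical(r1$p.value, r2$p.value)
  expect_gte(r1$p.value, 1 / 4001)
  expect_error(fisher_exact_rxc(tab, n_mc = 100), "seed")
  # MC close to the asymptotic chi-square reference on a moderate table
  expect_lt(abs(r1$p.value -
                  suppressWarnings(chisq.test(tab)$p.value)), 0.08)
})

test_that("p-value adjustment matches the closed forms and p.adjust", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bh"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  set.seed(707)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "bh"), p.adjust(p, "BH"))
    expect_equal(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
    expect_true(all(adjust_pvalues(p, "bh") <=
                      adjust_pvalues(p, "bonferroni") + 1e-12))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("qPCR score is 40 minus delta-CT with domain checks", {
  expect_equal(qpcr_expression_score(30, 20), 30)
  expect_equal(qpcr_expression_score(25, 25), 40)
  expect_equal(qpcr_expression_score(25.5, 18.25), 32.75)
  expect_error(qpcr_expression_score(41, 20), "\\(0, 40\\]")
  expect_error(qpcr_expression_score(30, 0), "\\(0, 40\\]")
})

test_that("every returned p-value is strictly positive", {
  expect_gt(rank_sum_test(rnorm(50, 10), rnorm(50), "greater")$p.value, 0)
  expect_gt(fisher_exact_2x2(matrix(c(50, 0, 0, 50), 2), "greater")$p.value,
            0)
  expect_gt(spearman_test(1:20, 1:20 + rnorm(20, sd = 1e-4),
                          "greater")$p.value, 0)
  expect_gt(signed_rank_test(rnorm(30, 5), 0, "greater")$p.value, 0)
})
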