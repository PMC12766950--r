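test_that("tissue eligibility is strictly more than min_lines", {
  em <- em_with_counts(c(20, 21, 30))
  expect_identical(eligible_tissues(em), c("tis2", "tis3"))
  expect_identical(eligible_tissues(em, min_lines = 29), "tis3")
})

test_that("quartile stratification: Q1 is highest, sizes differ by at most 1", {
  v <- setNames(1:8, paste0("s", 1:8))
  qa <- quartile_stratify(v)
  expect_setequal(names(qa)[qa == "Q1"], c("s8", "s7"))
  expect_setequal(names(qa)[qa == "Q4"], c("s1", "s2"))

  v10 <- setNames(rnorm(10), sprintf("s%02d", 1:10))
  qa10 <- quartile_stratify(v10)
  expect_identical(as.integer(table(qa10)[paste0("Q", 1:4)]),
                   c(3L, 3L, 2L, 2L))
  expect_error(quartile_stratify(setNames(1:3, letters[1:3])), "at least 4")
})

test_that("quartile ties break stably by sample id and partition is permutation-invariant", {
  v <- setNames(rep(1, 8), paste0("s", 1:8))
  qa <- quartile_stratify(v)
  expect_identical(as.integer(table(qa)), rep(2L, 4))
  expect_identical(names(qa)[qa == "Q1"], c("s1", "s2"))
  set.seed(9)
  v2 <- setNames(rnorm(12), sprintf("s%02d", 1:12))
  qa2 <- quartile_stratify(v2)
  perm <- sample(12)
  expect_identical(quartile_stratify(v2[perm])[names(qa2)], qa2)
})

test_that("Q1-vs-Q4 comparison is a one-sided rank-sum with the stated tails", {
  v <- setNames(1:12, sprintf("s%02d", 1:12))
  qa <- quartile_stratify(v)
  t_same <- setNames(rep(1, 12), names(v))
  expect_gte(q1_vs_q4_test(t_same, qa)$p.value, 0.5)
  # target strictly higher in every Q1 sample; |Q1| = |Q4| = 3
  tgt <- setNames(rep(0, 12), names(v))
  tgt[qa == "Q1"] <- 10 + 1:3
  expect_equal(q1_vs_q4_test(tgt, qa, exact = TRUE)$p.value, 1 / 20)
  # swapping Q1/Q4 labels flips to the complementary tail (tie-free data)
  set.seed(10)
  tgt2 <- setNames(rnorm(12), names(v))
  qa_sw <- qa
  qa_sw[qa == "Q1"] <- "Q4"; qa_sw[qa == "Q4"] <- "Q1"
  p1 <- q1_vs_q4_test(tgt2, qa, exact = TRUE)$p.value
  p2 <- q1_vs_q4_test(tgt2, qa_sw, exact = TRUE)$p.value
  wobs <- rank_sum_test(tgt2[qa == "Q1"], tgt2[qa == "Q4"],
                        "less", exact = TRUE)$p.value
  expect_equal(p2, wobs)
  expect_gte(p1 + p2, 1)  # tails overlap at the observed point
})

test_that("spearman screen: self-correlation, masking, missing genes", {
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 3, lines_per_tissue = 25, n_signature_genes = 2,
    n_null_genes = 2, planted_rho = 0.8, planted_tissue_fraction = 1,
    seed = 6))
  res <- spearman_screen(sim$em, c("WNT7B", sim$planted_genes, "ABSENT"),
                         "WNT7B", min_lines = 20)
  self <- res[res$gene == "WNT7B", ]
  expect_true(all(self$rho == 1))
  expect_identical(attr(res, "missing_genes"), "ABSENT")
  expect_identical(res$masked, is.na(res$rho_p) | res$rho_p > 0.05)
})

test_that("vectorized screen equals the scalar spearman test per pair", {
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 2, lines_per_tissue = 30, n_signature_genes = 3,
    n_null_genes = 3, seed = 13))
  res <- spearman_screen(sim$em, c(sim$planted_genes, sim$null_genes),
                         "WNT7B", min_lines = 20)
  for (i in sample(nrow(res), 6)) {
    cols <- names(sim$em$sample_tissue)[sim$em$sample_tissue ==
                                          res$tissue[i]]
    ref <- spearman_test(sim$em$values[res$gene[i], cols],
                         sim$em$values["WNT7B", cols], exact = FALSE)
    expect_equal(res$rho[i], unname(ref$statistic))
    expect_equal(res$rho_p[i], ref$p.value)
  }
})

test_that("screen is invariant to strictly monotone transforms of expression", {
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 2, lines_per_tissue = 25, n_signature_genes = 2,
    n_null_genes = 1, seed = 19))
  res1 <- spearman_screen(sim$em, sim$planted_genes, "WNT7B", 20)
  em2 <- expression_matrix(sim$em$values^2, sim$em$sample_tissue)
  res2 <- spearman_screen(em2, sim$planted_genes, "WNT7B", 20)
  expect_equal(res1$rho, res2$rho)
  expect_equal(res1$rho_p, res2$rho_p)
})

test_that("binary clustering uses asymmetric binary distance with total all-zero handling", {
  bm <- rbind(g1 = c(1, 1, 0), g2 = c(1, 0, 1), g3 = c(1, 1, 0),
              g4 = c(0, 0, 0), g5 = c(0, 0, 0))
  cl <- binary_cluster(bm)
  d <- as.matrix(stats::dist(bm, method = "binary"))
  expect_equal(d["g1", "g2"], 2 / 3)
  expect_equal(d["g1", "g3"], 0)
  # identical profiles sit adjacent in the leaf order
  io <- match(c("g1", "g3"), cl$order)
  expect_equal(abs(diff(io)), 1)
  iz <- match(c("g4", "g5"), cl$order)
  expect_equal(abs(diff(iz)), 1)
  # single gene: identity order, no tree
  one <- binary_cluster(bm[1, , drop = FALSE])
  expect_identical(one$order, "g1")
  expect_null(one$hclust)
})

test_that("leaf order matches a hand-computed average-linkage dendrogram", {
  # distances: A-B 0, {A,B}-C 2/3, D far from all, E all-zero
  bm <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), C = c(1, 0, 1, 0),
              D = c(0, 0, 0, 1), E = c(0, 0, 0, 0))
  cl <- binary_cluster(bm)
  # merge sequence by hand: (A,B) at 0; (A,B)+C at 2/3; D,E at 1 vs
  # E-to-(ABC) = 1 each, D-to-(ABC) = 1 -> (D,E) merges at 1, then all at 1
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$hclust$height[2], 2 / 3)
  ab <- match(c("A", "B"), cl$order)
  expect_equal(abs(diff(ab)), 1)
  abc <- range(match(c("A", "B", "C"), cl$order))
  expect_equal(diff(abc), 2)  # contiguous block of three
})

test_that("positivity counting uses rho > 0 and p < alpha with inclusive flagging", {
  res <- data.frame(
    tissue = rep(sprintf("t%d", 1:6), times = 2),
    gene = rep(c("gpos", "gneg"), each = 6),
    n = 30,
    rho = c(rep(0.5, 5), -0.5, rep(-0.5, 6)),
    rho_p = c(rep(0.01, 6), rep(0.01, 6)),
    stringsAsFactors = FALSE)
  res$masked <- res$rho_p > 0.05
  pos <- positive_tissue_count(res, min_tissues = 5, alpha = 0.05)
  expect_identical(unname(pos$counts["gpos"]), 5L)
  expect_identical(pos$flagged, "gpos")   # exactly 5 flags; negative never
})

test_that("mean target expression averages per eligible tissue", {
  em <- em_with_counts(c(21, 22))
  expect_equal(unname(mean_target_expression(em, "G")["tis1"]), mean(1:21))
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 3, lines_per_tissue = 25, n_signature_genes = 1,
    n_null_genes = 1, seed = 23))
  mt <- mean_target_expression(sim$em, "WNT7B", 20)
  for (tt in names(mt)) {
    expect_equal(unname(mt[tt]),
                 mean(sim$em$values["WNT7B",
                                    sim$em$sample_tissue == tt]))
  }
})

test_that("the full screen recovers planted genes and orders them contiguously", {
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 22, lines_per_tissue = 30, n_signature_genes = 10,
    n_null_genes = 100, planted_rho = 0.6,
    planted_tissue_fraction = 6 / 22, seed = 1))
  fit <- tissue_screen(sim$em, c(sim$planted_genes, sim$null_genes),
                       "WNT7B", q1q4 = FALSE)
  expect_true(all(sim$planted_genes %in% fit$flagged))
  expect_lte(sum(sim$null_genes %in% fit$flagged), 1)
  ix <- match(sim$planted_genes, fit$gene_order)
  expect_equal(diff(range(ix)), length(sim$planted_genes) - 1)
  # summary and print are well-formed
  s <- summary(fit)
  expect_identical(nrow(s), 110L)
  expect_output(print(fit), "flagged")
})

test_that("the screen's q1q4 column is the one-sided quartile comparison", {
  sim <- simulate_cell_line_matrix(screen_sim_config(
    n_tissues = 2, lines_per_tissue = 24, n_signature_genes = 2,
    n_null_genes = 0, planted_rho = 0.9, planted_tissue_fraction = 1,
    seed = 29))
  fit <- tissue_screen(sim$em, sim$planted_genes, "WNT7B")
  i <- 1L
  cols <- names(sim$em$sample_tissue)[sim$em$sample_tissue ==
                                        fit$results$tissue[i]]
  qa <- quartile_stratify(sim$em$values[fit$results$gene[i], cols])
  ref <- q1_vs_q4_test(sim$em$values["WNT7B", cols], qa)
  expect_equal(fit$results$q1q4_p[i], ref$p.value)
  # strong planted correlation: quartile test should reject
  expect_lt(median(fit$results$q1q4_p), 0.05)
})
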