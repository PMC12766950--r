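pb_fixture <- function(seed = 17, n_cells = 300, shift = log(2)) {
  sim <- simulate_single_cell(sc_sim_config(
    n_cells_per_genotype = 800, n_genes = 120, n_pathway_genes = 25,
    pathway_gene_shift = c(RZ = 0, RZK = shift), seed = seed))
  list(sim = sim,
       pbs = c(make_pseudobulks(sim$sc, "RZ", n_cells, 10, seed = seed + 1),
               make_pseudobulks(sim$sc, "RZK", n_cells, 10,
                                seed = seed + 2)))
}

test_that("pseudo-bulk totals conserve the sampled cells' counts", {
  fx <- pb_fixture()
  for (pb in fx$pbs[c(1, 5, 11)]) {
    expect_identical(pb$gene_totals,
                     rowSums(fx$sim$sc$counts[, pb$cells_used]))
    expect_equal(sum(pb$gene_totals),
                 sum(colSums(fx$sim$sc$counts[, pb$cells_used])))
    expect_length(pb$cells_used, 300)
    expect_false(anyDuplicated(pb$cells_used) > 0)
  }
})

test_that("pseudo-bulks with all cells collapse to the genotype column sum", {
  sim <- simulate_single_cell(sc_sim_config(
    n_cells_per_genotype = 50, n_genes = 30, n_pathway_genes = 5,
    seed = 41))
  pbs <- make_pseudobulks(sim$sc, "RZ", n_cells = 50, n_reps = 3, seed = 2)
  full <- rowSums(sim$sc$counts[, sim$sc$cell_genotype == "RZ"])
  for (pb in pbs) expect_identical(pb$gene_totals, full)
})

test_that("pseudo-bulk sampling is seeded and insufficient cells error", {
  sim <- simulate_single_cell(sc_sim_config(
    n_cells_per_genotype = 60, n_genes = 20, n_pathway_genes = 5,
    seed = 43))
  a <- make_pseudobulks(sim$sc, "RZ", 30, 4, seed = 9)
  b <- make_pseudobulks(sim$sc, "RZ", 30, 4, seed = 9)
  d <- make_pseudobulks(sim$sc, "RZ", 30, 4, seed = 10)
  expect_identical(lapply(a, `[[`, "cells_used"),
                   lapply(b, `[[`, "cells_used"))
  expect_false(identical(lapply(a, `[[`, "cells_used"),
                         lapply(d, `[[`, "cells_used")))
  expect_error(make_pseudobulks(sim$sc, "RZ", 100, 2, seed = 1),
               "at least")
})

test_that("ssGSEA equals the position-by-position running-sum oracle", {
  set.seed(53)
  for (i in 1:40) {
    prof <- setNames(rnorm(20), sprintf("g%02d", 1:20))
    mem <- sample(names(prof), sample(5:10, 1))
    mine <- ssgsea_score(prof, gene_set("s", mem), times = 0)$es
    expect_equal(mine, oracle_ssgsea_es(prof, mem))
  }
})

test_that("ssGSEA limit cases: full set scores 1, single top hit by hand", {
  prof <- setNames(runif(10, 1, 2), letters[1:10])
  expect_equal(ssgsea_score(prof, gene_set("all", letters[1:10]),
                            times = 0)$es, 1)
  # single hit at the top rank: ES = 1 reached right after rank 1
  prof2 <- setNames(10:1, letters[1:10])
  expect_equal(ssgsea_score(prof2, gene_set("top", "a"), min_set_size = 1,
                            times = 0)$es, 1)
  # hand-computed: hit at rank 2 with uniform weights, w = 0
  prof3 <- setNames(rep(1, 10), letters[1:10])  # ties -> id order a..j
  es <- ssgsea_score(prof3, gene_set("b2", "b"), min_set_size = 1,
                     times = 0, w = 0)$es
  expect_equal(es, 1 - 1 / 9)   # one miss step then the hit
})

test_that("profile-shift invariance holds only for w = 0", {
  # members at the extremes so the maximum deviation sits mid-set, where the
  # relative hit weights matter
  prof <- setNames(as.numeric(10:1), letters[1:10])
  mem <- c("a", "j")
  s0 <- ssgsea_score(prof, gene_set("s", mem), min_set_size = 2, times = 0,
                     w = 0)$es
  s0_shift <- ssgsea_score(prof + 5, gene_set("s", mem), min_set_size = 2,
                           times = 0, w = 0)$es
  expect_equal(s0, s0_shift)
  s1 <- ssgsea_score(prof, gene_set("s", mem), min_set_size = 2, times = 0,
                     w = 1)$es
  s1_shift <- ssgsea_score(prof + 5, gene_set("s", mem), min_set_size = 2,
                           times = 0, w = 1)$es
  expect_equal(s1, 10 / 11)        # weight 10 of total 11 at the top rank
  expect_equal(s1_shift, 15 / 21)  # constant shifts reweight the hits
  expect_false(isTRUE(all.equal(s1, s1_shift)))
})

test_that("signed sets score as the difference of subset enrichments", {
  set.seed(61)
  prof <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  pos <- sample(names(prof), 6)
  neg <- sample(setdiff(names(prof), pos), 5)
  sgs <- signed_gene_set("signed", setNames(c(rep(1, 6), rep(-1, 5)),
                                            c(pos, neg)))
  es <- ssgsea_score(prof, sgs, times = 0)$es
  expect_equal(es, oracle_ssgsea_es(prof, pos) - oracle_ssgsea_es(prof, neg))
})

test_that("the permutation null is calibrated and floor-corrected", {
  set.seed(67)
  ps <- replicate(100, {
    prof <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    mem <- sample(names(prof), 10)   # same distribution as background
    ssgsea_score(prof, gene_set("null", mem), times = 200,
                 seed = sample.int(1e6, 1))$perm_p
  })
  expect_gte(mean(ps > 0.05), 0.90)
  expect_true(all(ps >= 1 / 201))
  # small sets fall below the floor and are reported absent
  prof <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  expect_null(ssgsea_score(prof, gene_set("tiny", names(prof)[1:3]),
                           min_set_size = 5, times = 0))
})

test_that("pathway scoring table: identical inputs give identical rows, absent sets vanish", {
  fx <- pb_fixture(seed = 71, shift = 0)
  pb2 <- fx$pbs[c(1, 1)]
  gs <- gene_set("MAPK", fx$sim$truth$pathway_genes)
  tbl <- score_pathways(pb2, list(gs), times = 100, seed = 5)
  expect_equal(tbl$es[1], tbl$es[2])
  expect_equal(tbl$perm_p[1], tbl$perm_p[2])
  missing_set <- gene_set("ABSENT", sprintf("zz%d", 1:10))
  tbl2 <- score_pathways(fx$pbs[1:2], list(gs, missing_set), times = 0,
                         seed = 1)
  expect_identical(unique(tbl2$set), "MAPK")
  expect_identical(tbl2$n_genes_used, rep(25L, 2))
})

test_that("a planted pathway shift separates genotypes in ES and rank-sum p", {
  fx <- pb_fixture(seed = 73, shift = log(2))
  gs <- gene_set("MAPK", fx$sim$truth$pathway_genes)
  tbl <- score_pathways(fx$pbs, list(gs), times = 0, seed = 1)
  expect_gt(mean(tbl$es[tbl$genotype == "RZK"]),
            mean(tbl$es[tbl$genotype == "RZ"]))
  cmp <- compare_pathway_activity(tbl, "RZK", "RZ", "MAPK")
  expect_lt(cmp$p.value, 0.05)
  # identical score vectors: p >= 0.5
  same <- tbl
  same$es <- rep(1, nrow(same))
  expect_gte(compare_pathway_activity(same, "RZK", "RZ", "MAPK")$p.value,
             0.5)
})

test_that("complete separation with B = 10 gives the exact minimum p", {
  tbl <- data.frame(sample = c(paste0("A_", 1:10), paste0("B_", 1:10)),
                    genotype = rep(c("A", "B"), each = 10),
                    replicate = rep(1:10, 2), set = "S",
                    es = c(11:20, 1:10), perm_p = NA, n_genes_used = 10,
                    stringsAsFactors = FALSE)
  class(tbl) <- c("pathway_scores", "data.frame")
  cmp <- compare_pathway_activity(tbl, "A", "B", "S", exact = TRUE)
  expect_equal(cmp$p.value, 1 / choose(20, 10))
  expect_error(compare_pathway_activity(tbl, "A", "B", "nope"), "set")
})
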