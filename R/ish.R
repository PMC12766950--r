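#' Semi-quantitative ISH class of a cell
#'
#' Ordinal RNAscope-style score from dots per cell and the fraction of dots
#' lying in clusters. The overlapping legend clauses are resolved by fixed
#' precedence, evaluated top down so every cell gets exactly one class:
#'
#' * Class 4: more than 15 dots;
#' * Class 3: 10-15 dots, or cluster fraction above 0.10 with at least 4
#'   dots (the cluster escalator never promotes an isolated 1-3-dot cell);
#' * Class 2: 4-9 dots (with no or very few clusters, i.e. fraction at most
#'   0.10);
#' * Class 1: 1-3 dots;
#' * Class 0: no dots.
#'
#' The legend's "less than 1 dot per 10 cells" reading of Class 0 is a
#' field-level average; see the `field_level` mode of [class_distribution].
#'
#' @param dots non-negative integer vector of dot counts.
#' @param cluster_fraction fraction of dots in clusters, in \[0, 1\]
#'   (recycled).
#' @return Integer vector of classes 0-4.
#' @examples
#' classify_ish_cell(c(0, 2, 8, 12, 20), c(0, 0, 0, 0, 0))
#' classify_ish_cell(8, 0.2)   # cluster escalator: Class 3
#' @export
classify_ish_cell <- function(dots, cluster_fraction = 0) {
  if (any(dots < 0) || any(dots != round(dots)))
    stop("dots must be non-negative integers")
  if (any(cluster_fraction < 0) || any(cluster_fraction > 1))
    stop("cluster_fraction must lie in [0, 1]")
  n <- max(length(dots), length(cluster_fraction))
  dots <- rep_len(dots, n)
  cf <- rep_len(cluster_fraction, n)
  ifelse(dots > 15, 4L,
         ifelse(dots >= 10 | (cf > 0.10 & dots >= 4), 3L,
                ifelse(dots >= 4, 2L,
                       ifelse(dots >= 1, 1L, 0L))))
}

#' Tally ISH classes per condition
#'
#' @param observations data.frame with columns `condition`, `dots`,
#'   `cluster_fraction` (see [read_ish_observations]).
#' @param field_level if TRUE, conditions whose mean dot count is below 0.1
#'   dots/cell have their Class 1 cells reassigned to Class 0, implementing
#'   the field-level "less than 1 dot per 10 cells" reading of Class 0.
#' @return Matrix of class `class_distribution`: conditions x classes
#'   `"0"`..`"4"`; rows sum to the per-condition cell counts.
#' @export
class_distribution <- function(observations, field_level = FALSE) {
  conds <- unique(observations$condition)
  out <- matrix(0L, nrow = length(conds), ncol = 5L,
                dimnames = list(conds, as.character(0:4)))
  for (cond in conds) {
    sub <- observations[observations$condition == cond, , drop = FALSE]
    cls <- classify_ish_cell(sub$dots, sub$cluster_fraction)
    if (field_level && mean(sub$dots) < 0.1) cls[cls == 1L] <- 0L
    tab <- table(factor(cls, levels = 0:4))
    out[cond, ] <- as.integer(tab)
  }
  class(out) <- c("class_distribution", class(out))
  out
}

#' Compare ISH class distributions between two conditions
#'
#' Builds the 2 x 5 class contingency table and applies the exact r x c
#' contingency test ([fisher_exact_rxc]); classes with zero counts in both
#' conditions are dropped by that test with a warning.
#'
#' @param cd a `class_distribution` matrix.
#' @param cond_a,cond_b condition labels (row names of `cd`).
#' @param n_mc,seed Monte-Carlo controls passed through for large tables.
#' @return A [test_result] (two-sided; symmetric in condition order).
#' @export
compare_class_distributions <- function(cd, cond_a, cond_b, n_mc = 10000,
                                        seed = NULL) {
  for (cond in c(cond_a, cond_b))
    if (!cond %in% rownames(cd)) stop("condition absent: ", cond)
  tab <- cd[c(cond_a, cond_b), , drop = FALSE]
  fisher_exact_rxc(tab, n_mc = n_mc, seed = seed)
}

#' Fraction of cells expressing a gene
#'
#' A cell expresses the gene when its UMI count is strictly positive — the
#' count threshold is exactly "non-zero", with no abundance cutoff.
#'
#' @param sc a [single_cell_counts].
#' @param gene gene id present in the counts.
#' @return data.frame: `genotype`, `cluster`, `n_cells`, `n_expressing`,
#'   `fraction`.
#' @export
expressing_fraction <- function(sc, gene) {
  stopifnot(inherits(sc, "single_cell_counts"))
  if (!gene %in% rownames(sc$counts)) stop("gene absent: ", gene)
  expr <- sc$counts[gene, ] > 0
  key <- paste(sc$cell_genotype, sc$cell_cluster, sep = "\r")
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(genotype = vapply(parts, `[[`, character(1), 1L),
             cluster = vapply(parts, `[[`, character(1), 2L),
             n_cells = vapply(keys, function(k) sum(key == k), integer(1)),
             n_expressing = vapply(keys, function(k) sum(expr[key == k]),
                                   integer(1)),
             fraction = vapply(keys, function(k) mean(expr[key == k]),
                               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test an expressing-fraction difference between genotypes in one cluster
#'
#' Two-sided Fisher's exact test on the 2 x 2 table of expressing /
#' non-expressing cells by genotype, within one cluster.
#'
#' @param sc a [single_cell_counts].
#' @param gene gene id.
#' @param cluster cluster label.
#' @param genotype_a,genotype_b genotype labels, both with cells in the
#'   cluster.
#' @return A [test_result] with the odds ratio as effect size.
#' @export
expressing_fraction_test <- function(sc, gene, cluster, genotype_a,
                                     genotype_b) {
  stopifnot(inherits(sc, "single_cell_counts"))
  if (!gene %in% rownames(sc$counts)) stop("gene absent: ", gene)
  expr <- sc$counts[gene, ] > 0
  sel_a <- sc$cell_genotype == genotype_a & sc$cell_cluster == cluster
  sel_b <- sc$cell_genotype == genotype_b & sc$cell_cluster == cluster
  if (!any(sel_a) || !any(sel_b))
    stop("both genotypes need cells in cluster ", cluster)
  tab <- matrix(c(sum(expr[sel_a]), sum(!expr[sel_a]),
                  sum(expr[sel_b]), sum(!expr[sel_b])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(genotype_a, genotype_b),
                                c("expressing", "non_expressing")))
  fisher_exact_2x2(tab, alternative = "two.sided")
}
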