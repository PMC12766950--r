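#' Pseudo-bulk samples from single-cell counts
#'
#' Aggregates randomly selected cells of one genotype into pseudo-bulk
#' profiles: each replicate draws `n_cells` cells without replacement
#' (replicates are drawn independently and may overlap) and sums their UMI
#' counts per gene. Fully reproducible under `seed`.
#'
#' @param sc a [single_cell_counts].
#' @param genotype genotype label with at least `n_cells` cells.
#' @param n_cells cells aggregated per replicate (default 500).
#' @param n_reps number of replicates (default 10).
#' @param seed integer RNG seed (mandatory).
#' @return List of `pseudo_bulk` objects: `genotype`, `replicate`,
#'   `gene_totals` (named integer vector), `cells_used`, `seed`.
#' @export
make_pseudobulks <- function(sc, genotype, n_cells = 500, n_reps = 10,
                             seed) {
  stopifnot(inherits(sc, "single_cell_counts"))
  if (missing(seed)) stop("seed is mandatory")
  cells <- colnames(sc$counts)[sc$cell_genotype == genotype]
  if (length(cells) == 0L) stop("genotype absent: ", genotype)
  if (length(cells) < n_cells)
    stop("genotype ", genotype, " has ", length(cells),
         " cells; need at least ", n_cells)
  .with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      used <- sample(cells, n_cells)
      structure(list(genotype = genotype, replicate = b,
                     gene_totals = rowSums(sc$counts[, used, drop = FALSE]),
                     cells_used = used, seed = as.integer(seed)),
                class = "pseudo_bulk")
    })
  })
}

# ES of the weighted running sum, visiting only hit positions.
# Between hits the sum falls linearly by the miss step, so the extreme
# deviations occur immediately after a hit (maximum) or immediately before
# one / at the profile end (minimum). ES is the deviation largest in
# absolute value, sign preserved.
.running_sum_es <- function(hitpos, whits, n_genes) {
  h <- length(hitpos)
  m <- if (n_genes > h) 1 / (n_genes - h) else 0
  sw <- sum(whits)
  cum <- if (sw > 0) cumsum(whits) / sw else seq_len(h) / h
  after <- cum - m * (hitpos - seq_len(h))
  before <- c(0, cum[-h]) - m * (hitpos - seq_len(h))
  maxdev <- max(after)
  mindev <- min(before, 0)
  if (maxdev >= -mindev) maxdev else mindev
}

.es_for_members <- function(ranked_genes, w_abs, members) {
  hitpos <- which(ranked_genes %in% members)
  if (length(hitpos) == 0L) return(0)
  .running_sum_es(hitpos, w_abs[hitpos], length(ranked_genes))
}

#' Single-sample GSEA score with a gene-permutation null
#'
#' Weighted Kolmogorov-Smirnov-style running-sum enrichment: genes are ranked
#' by the profile in descending order (ties broken lexicographically by gene
#' id); a hit at rank i increments the running sum by
#' `|profile_i|^w / sum(|profile_hits|^w)` and a miss decrements it by
#' `1 / (N - n_hits)`; the enrichment score ES is the maximum deviation of
#' the running sum from zero (sign preserved; when the positive and negative
#' deviations tie exactly in magnitude the positive one is reported). Signed
#' sets are scored as
#' `ES(positive members) - ES(negative members)`. The null permutes gene
#' labels of the profile: `times` random hit sets of the same size are
#' scored, and `perm_p = (k + 1) / (times + 1)` with `k` the number of
#' permutations reaching `ES >= observed` (one-sided, enrichment).
#'
#' @param profile named numeric vector over genes (one sample's expression).
#' @param gene_set a [gene_set] or [signed_gene_set].
#' @param min_set_size minimum overlap with the profile's genes (default 5,
#'   the screening floor for small sets); sets below it return `NULL`.
#' @param times permutations for the null (default 10000); 0 skips the null
#'   (`perm_p = NA`).
#' @param seed integer RNG seed (required when `times > 0`).
#' @param w weighting exponent on `|profile|` (default 1, the classic
#'   weighted statistic; `w = 0` gives the unweighted KS form).
#' @return List `es`, `perm_p`, `n_genes_used`, or `NULL` when the overlap is
#'   below `min_set_size`.
#' @export
ssgsea_score <- function(profile, gene_set, min_set_size = 5, times = 10000,
                         seed = NULL, w = 1) {
  if (is.null(names(profile))) stop("profile must be named by gene id")
  n <- length(profile)
  ord <- order(-profile, names(profile))
  ranked <- names(profile)[ord]
  w_abs <- abs(profile[ord])^w

  signed <- inherits(gene_set, "signed_gene_set")
  if (signed) {
    members <- names(gene_set$weights)[names(gene_set$weights) %in% ranked]
    pos <- intersect(names(gene_set$weights)[gene_set$weights > 0], ranked)
    neg <- intersect(names(gene_set$weights)[gene_set$weights < 0], ranked)
  } else {
    stopifnot(inherits(gene_set, "gene_set"))
    members <- intersect(gene_set$members, ranked)
  }
  n_used <- length(members)
  if (n_used < min_set_size) return(NULL)

  es_obs <- if (signed) {
    .es_for_members(ranked, w_abs, pos) - .es_for_members(ranked, w_abs, neg)
  } else {
    .es_for_members(ranked, w_abs, members)
  }

  perm_p <- NA_real_
  if (times > 0) {
    if (is.null(seed)) stop("seed is required when times > 0")
    es_perm <- .with_seed(seed, {
      vapply(seq_len(times), function(b) {
        if (signed) {
          idx <- sample.int(n, length(pos) + length(neg))
          hp <- sort(idx[seq_along(pos)])
          hn <- sort(idx[-seq_along(pos)])
          ep <- if (length(hp)) .running_sum_es(hp, w_abs[hp], n) else 0
          en <- if (length(hn)) .running_sum_es(hn, w_abs[hn], n) else 0
          ep - en
        } else {
          hp <- sort(sample.int(n, n_used))
          .running_sum_es(hp, w_abs[hp], n)
        }
      }, numeric(1))
    })
    k <- sum(es_perm >= es_obs - 1e-12)
    perm_p <- (k + 1) / (times + 1)
  }
  list(es = es_obs, perm_p = perm_p, n_genes_used = n_used)
}

#' Score pseudo-bulk samples against pathway gene sets
#'
#' Normalizes each pseudo-bulk profile (counts per 10k, `log1p`) and scores
#' it with [ssgsea_score] against every set. Sets whose overlap with the
#' profiled genes falls below `min_set_size` are absent from the table.
#' Permutation seeds are derived deterministically from `seed` per set, so
#' all samples share one fixed permutation ensemble per set (a common null:
#' identical profiles receive identical permutation p-values).
#'
#' @param pbs list of `pseudo_bulk` objects (see [make_pseudobulks]).
#' @param sets list of [gene_set] / [signed_gene_set] objects.
#' @param min_set_size,times,w passed to [ssgsea_score] (defaults 5, 10000,
#'   1).
#' @param seed integer base seed (required when `times > 0`).
#' @param normalization only `"cp10k_log1p"` is provided.
#' @return data.frame of class `pathway_scores`: `sample`, `genotype`,
#'   `replicate`, `set`, `es`, `perm_p`, `n_genes_used`.
#' @export
score_pathways <- function(pbs, sets, min_set_size = 5, times = 10000,
                           seed = NULL, w = 1,
                           normalization = "cp10k_log1p") {
  stopifnot(length(pbs) >= 1L)
  normalization <- match.arg(normalization)
  rows <- list()
  for (i in seq_along(pbs)) {
    pb <- pbs[[i]]
    stopifnot(inherits(pb, "pseudo_bulk"))
    prof <- cp10k_log1p(matrix(pb$gene_totals, ncol = 1,
                               dimnames = list(names(pb$gene_totals),
                                               "pb")))[, 1]
    for (j in seq_along(sets)) {
      sc_seed <- if (is.null(seed)) NULL
      else as.integer((seed + j) %% .Machine$integer.max)
      res <- ssgsea_score(prof, sets[[j]], min_set_size = min_set_size,
                          times = times, seed = sc_seed, w = w)
      if (is.null(res)) next
      set_name <- sets[[j]]$name
      rows[[length(rows) + 1L]] <-
        data.frame(sample = paste0(pb$genotype, "_", pb$replicate),
                   genotype = pb$genotype, replicate = pb$replicate,
                   set = set_name, es = res$es, perm_p = res$perm_p,
                   n_genes_used = res$n_genes_used,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), genotype = character(0),
               replicate = integer(0), set = character(0), es = numeric(0),
               perm_p = numeric(0), n_genes_used = integer(0))
  rownames(out) <- NULL
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Compare pathway activity between genotypes
#'
#' One-sided rank-sum test on the per-replicate enrichment scores of one
#' gene set: alternative "greater" for `genotype_a` above `genotype_b`.
#'
#' @param tbl a `pathway_scores` table from [score_pathways].
#' @param genotype_a,genotype_b genotype labels present in the table.
#' @param set_name gene set to compare.
#' @param exact use the exact enumeration mode of [rank_sum_test].
#' @return A [test_result].
#' @export
compare_pathway_activity <- function(tbl, genotype_a, genotype_b, set_name,
                                     exact = FALSE) {
  sub <- tbl[tbl$set == set_name, , drop = FALSE]
  if (nrow(sub) == 0L) stop("set not present in score table: ", set_name)
  x <- sub$es[sub$genotype == genotype_a]
  y <- sub$es[sub$genotype == genotype_b]
  if (length(x) == 0L || length(y) == 0L)
    stop("both genotypes must be scored for set ", set_name)
  rank_sum_test(x, y, alternative = "greater", exact = exact)
}
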