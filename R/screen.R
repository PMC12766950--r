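#' @importFrom stats dist hclust
#' @importFrom graphics axis image par
#' @importFrom grDevices colorRampPalette
NULL

#' Tissues with enough cell lines for the screen
#'
#' Eligibility requires strictly more than `min_lines` samples per tissue
#' ("over 20 cell lines": a tissue with exactly 20 is excluded).
#'
#' @param em an [expression_matrix].
#' @param min_lines exclusive lower bound on lines per tissue (default 20).
#' @return Character vector of eligible tissue labels (first-appearance
#'   order).
#' @export
eligible_tissues <- function(em, min_lines = 20) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- table(factor(em$sample_tissue, levels = unique(em$sample_tissue)))
  names(tab)[tab > min_lines]
}

#' Quartile stratification of one tissue's samples
#'
#' Ranks samples by expression in descending order — Q1 is the HIGHEST
#' quartile — and fills Q1..Q4 in rank order with sizes differing by at most
#' one (each quartile takes `ceiling(remaining / groups_left)` samples). Ties
#' are broken deterministically by sample id, so the assignment is stable
#' under permutation of the input.
#'
#' @param values named numeric vector (names are sample ids), length >= 4.
#' @return Named character vector of quartile labels `"Q1"`..`"Q4"`.
#' @export
quartile_stratify <- function(values) {
  if (is.null(names(values))) stop("values must be named by sample id")
  n <- length(values)
  if (n < 4L) stop("need at least 4 samples to form quartiles")
  ord <- order(-values, names(values))
  sizes <- integer(4)
  left <- n
  for (k in 1:4) {
    sizes[k] <- ceiling(left / (5 - k))
    left <- left - sizes[k]
  }
  labels <- rep(paste0("Q", 1:4), times = sizes)
  out <- character(n)
  out[ord] <- labels
  names(out) <- names(values)
  out
}

#' Compare target expression between the highest and lowest quartiles
#'
#' One-sided rank-sum test of the target being higher in Q1 (highest
#' stratifying-gene quartile) than in Q4.
#'
#' @param target_values named numeric vector of target expression.
#' @param qa quartile assignment from [quartile_stratify] over the same
#'   sample ids.
#' @param exact use the exact enumeration mode of [rank_sum_test].
#' @return A [test_result].
#' @export
q1_vs_q4_test <- function(target_values, qa, exact = FALSE) {
  q1 <- names(qa)[qa == "Q1"]; q4 <- names(qa)[qa == "Q4"]
  if (length(q1) == 0L || length(q4) == 0L)
    stop("Q1 and Q4 must be non-empty")
  rank_sum_test(target_values[q1], target_values[q4],
                alternative = "greater", exact = exact)
}

# vectorized Spearman rho + two-sided t-approximation p for one tissue:
# genes x samples matrix against a target vector. Constant rows give NA.
.spearman_block <- function(gene_vals, target_vals) {
  n <- length(target_vals)
  rt <- rank(target_vals)
  rg <- t(apply(gene_vals, 1L, rank))
  if (nrow(gene_vals) == 1L) rg <- matrix(rg, nrow = 1L)
  suppressWarnings(rho <- as.vector(stats::cor(t(rg), rt)))
  rho[apply(gene_vals, 1L, function(v) length(unique(v)) == 1L)] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tstat[abs(rho) >= 1] <- sign(rho[abs(rho) >= 1]) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(rho = rho, p = p)
}

#' Per-tissue Spearman correlations of signature genes with a target gene
#'
#' For each eligible tissue and each signature gene present in the matrix,
#' computes the Spearman correlation with the target and its two-sided
#' p-value (t approximation for tissues with more than 10 lines, exact
#' permutation enumeration otherwise), plus the significance mask
#' `masked = (p > alpha)` used for display and clustering. The mask uses the
#' UNADJUSTED p-value by default; `adjust = "bh"` switches the mask (not the
#' reported p) to Benjamini-Hochberg-adjusted values across the whole grid.
#'
#' @param em an [expression_matrix].
#' @param signature a `signature_result` or character vector of gene ids.
#' @param target_gene target gene id (must be present in the matrix).
#' @param min_lines tissue eligibility bound (exclusive), default 20.
#' @param alpha significance level for the mask, default 0.05.
#' @param adjust `"none"` (default) or `"bh"` for the mask.
#' @return data.frame: tissue, gene, n, rho, rho_p, masked. Genes absent
#'   from the matrix are recorded in the `missing_genes` attribute.
#' @export
spearman_screen <- function(em, signature, target_gene = "WNT7B",
                            min_lines = 20, alpha = 0.05,
                            adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(em, "expression_matrix"))
  genes <- if (inherits(signature, "signature_result")) signature$genes
  else as.character(signature)
  if (!target_gene %in% rownames(em$values))
    stop("target gene not in matrix: ", target_gene)
  missing_genes <- setdiff(genes, rownames(em$values))
  genes <- genes[genes %in% rownames(em$values)]
  if (length(genes) == 0L) stop("no signature genes present in the matrix")
  tissues <- eligible_tissues(em, min_lines)
  if (length(tissues) == 0L) stop("no tissue passes the eligibility bound")

  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    cols <- names(em$sample_tissue)[em$sample_tissue == tissues[ti]]
    tv <- em$values[target_gene, cols]
    gv <- em$values[genes, cols, drop = FALSE]
    n <- length(cols)
    if (n > 10L) {
      blk <- .spearman_block(gv, tv)
      rho <- blk$rho; p <- blk$p
    } else {
      rho <- p <- rep(NA_real_, length(genes))
      for (gi in seq_along(genes)) {
        res <- tryCatch(spearman_test(gv[gi, ], tv),
                        kraswnt_undefined_error = function(e) NULL)
        if (!is.null(res)) {
          rho[gi] <- res$statistic[["rho"]]; p[gi] <- res$p.value
        }
      }
    }
    out[[ti]] <- data.frame(tissue = tissues[ti], gene = genes, n = n,
                            rho = rho, rho_p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  pm <- if (adjust == "bh") {
    ok <- !is.na(res$rho_p)
    padj <- rep(NA_real_, nrow(res))
    padj[ok] <- adjust_pvalues(res$rho_p[ok], "bh")
    padj
  } else res$rho_p
  res$masked <- is.na(pm) | pm > alpha
  rownames(res) <- NULL
  attr(res, "missing_genes") <- missing_genes
  attr(res, "alpha") <- alpha
  res
}

#' Cluster genes by their binary significance profiles
#'
#' Encodes each gene as a 0/1 vector of per-tissue significance
#' (1 = unmasked, p < alpha), computes asymmetric binary (Jaccard) distances
#' — mismatches over positions where either profile is 1 — and clusters with
#' average-linkage agglomeration. Two all-zero profiles, undefined under the
#' textbook definition, are assigned distance 0 so the clustering stays
#' total. The leaf order is deterministic given the input order.
#'
#' @param results data.frame from [spearman_screen] (or any with columns
#'   gene, tissue, masked), or a genes x tissues 0/1 matrix.
#' @return List: `order` (gene ids in leaf order), `hclust` (the tree, or
#'   `NULL` for a single gene), `binary` (the profile matrix).
#' @export
binary_cluster <- function(results) {
  if (is.matrix(results)) {
    bm <- (results != 0) * 1
  } else {
    genes <- unique(results$gene)
    tissues <- unique(results$tissue)
    bm <- matrix(0, nrow = length(genes), ncol = length(tissues),
                 dimnames = list(genes, tissues))
    bm[cbind(match(results$gene, genes), match(results$tissue, tissues))] <-
      as.numeric(!results$masked)
  }
  if (nrow(bm) < 2L)
    return(list(order = rownames(bm), hclust = NULL, binary = bm))
  d <- stats::dist(bm, method = "binary")
  d[is.na(d)] <- 0     # pairs of all-zero profiles: no evidence, distance 0
  hc <- stats::hclust(d, method = "average")
  list(order = rownames(bm)[hc$order], hclust = hc, binary = bm)
}

#' Count positive-significant tissues per gene
#'
#' A tissue counts for a gene when the correlation is positive and unmasked
#' (`rho > 0` and `rho_p < alpha`); genes reaching `min_tissues` (inclusive:
#' "at least 5") are flagged.
#'
#' @param results data.frame from [spearman_screen].
#' @param min_tissues inclusive flagging bound, default 5.
#' @param alpha significance level, defaulting to the screen's.
#' @return List: `counts` (named integer per gene), `flagged` (gene ids with
#'   `counts >= min_tissues`).
#' @export
positive_tissue_count <- function(results, min_tissues = 5, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(results, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  ok <- !is.na(results$rho) & results$rho > 0 & results$rho_p < alpha
  genes <- unique(results$gene)
  counts <- vapply(genes, function(g) sum(ok[results$gene == g]), integer(1))
  list(counts = counts, flagged = genes[counts >= min_tissues])
}

#' Mean target expression per eligible tissue
#'
#' @param em an [expression_matrix].
#' @param target_gene gene id present in the matrix.
#' @param min_lines tissue eligibility bound (exclusive), default 20.
#' @return Named numeric vector of per-tissue arithmetic means.
#' @export
mean_target_expression <- function(em, target_gene = "WNT7B",
                                   min_lines = 20) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!target_gene %in% rownames(em$values))
    stop("target gene not in matrix: ", target_gene)
  tissues <- eligible_tissues(em, min_lines)
  vapply(tissues, function(tt) {
    mean(em$values[target_gene, em$sample_tissue == tt])
  }, numeric(1))
}

#' Pan-cancer tissue-stratified correlation screen
#'
#' The package's central fit: for a signature gene set and a target WNT
#' ligand, screens every eligible tissue (more than `min_lines` cell lines)
#' for rank correlation between each signature gene and the target, tests
#' target expression between the highest (Q1) and lowest (Q4)
#' signature-gene quartiles, clusters genes by their binary significance
#' profiles, and flags genes positively correlated with the target in at
#' least `min_tissues` tissues.
#'
#' @param em an [expression_matrix] (log2(TPM + 1)-like values).
#' @param signature a `signature_result` or character vector of gene ids.
#' @param target_gene target gene id, default `"WNT7B"`.
#' @param min_lines tissue eligibility: strictly more than this many lines.
#' @param alpha significance level for masking and positivity (default
#'   0.05, unadjusted; see `adjust`).
#' @param min_tissues inclusive bound for flagging a gene (default 5).
#' @param adjust `"none"` (default) or `"bh"`: multiplicity handling for the
#'   significance mask.
#' @param q1q4 compute the per-(tissue, gene) Q1-vs-Q4 rank-sum test
#'   (default TRUE; disable for very large null screens).
#' @return An object of class `tissue_screen` with components `results`
#'   (long data.frame: tissue, gene, n, rho, rho_p, masked, q1q4_p,
#'   direction), `mean_target`, `positive_counts`, `flagged`, `gene_order`,
#'   `hclust`, `binary`, `missing_genes` and `params`. Methods: `print`,
#'   `summary`, `plot`.
#' @examples
#' sim <- simulate_cell_line_matrix(screen_sim_config(
#'   n_tissues = 4, lines_per_tissue = 25, n_signature_genes = 3,
#'   n_null_genes = 2, planted_rho = 0.8, planted_tissue_fraction = 0.5,
#'   seed = 1))
#' fit <- tissue_screen(sim$em, c(sim$planted_genes, sim$null_genes),
#'                      min_lines = 20, min_tissues = 2)
#' print(fit)
#' @export
tissue_screen <- function(em, signature, target_gene = "WNT7B",
                          min_lines = 20, alpha = 0.05, min_tissues = 5,
                          adjust = c("none", "bh"), q1q4 = TRUE) {
  adjust <- match.arg(adjust)
  res <- spearman_screen(em, signature, target_gene, min_lines, alpha,
                         adjust)
  if (q1q4) {
    q1q4_p <- numeric(nrow(res))
    for (i in seq_len(nrow(res))) {
      cols <- names(em$sample_tissue)[em$sample_tissue == res$tissue[i]]
      gv <- em$values[res$gene[i], cols]
      tv <- em$values[target_gene, cols]
      qa <- quartile_stratify(gv)
      q1q4_p[i] <- q1_vs_q4_test(tv, qa)$p.value
    }
    res$q1q4_p <- q1q4_p
  } else {
    res$q1q4_p <- NA_real_
  }
  res$direction <- ifelse(is.na(res$rho), NA_character_,
                          ifelse(res$rho >= 0, "positive", "negative"))
  cl <- binary_cluster(res)
  pos <- positive_tissue_count(res, min_tissues, alpha)
  structure(list(results = res,
                 mean_target = mean_target_expression(em, target_gene,
                                                      min_lines),
                 positive_counts = pos$counts, flagged = pos$flagged,
                 gene_order = cl$order, hclust = cl$hclust,
                 binary = cl$binary,
                 missing_genes = attr(res, "missing_genes"),
                 params = list(target_gene = target_gene,
                               min_lines = min_lines, alpha = alpha,
                               min_tissues = min_tissues, adjust = adjust),
                 call = match.call()),
            class = "tissue_screen")
}

#' @export
print.tissue_screen <- function(x, ...) {
  nt <- length(unique(x$results$tissue))
  ng <- length(unique(x$results$gene))
  cat("Tissue-stratified correlation screen\n")
  cat("  target:", x$params$target_gene, "|", ng, "genes x", nt,
      "eligible tissues (>", x$params$min_lines, "lines)\n")
  cat("  flagged (positive, p <", x$params$alpha, "in >=",
      x$params$min_tissues, "tissues):", length(x$flagged), "of", ng, "\n")
  if (length(x$flagged))
    cat("   ", paste(x$flagged, collapse = ", "), "\n")
  if (length(x$missing_genes))
    cat("  missing from matrix:", paste(x$missing_genes, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.tissue_screen <- function(object, ...) {
  genes <- unique(object$results$gene)
  data.frame(gene = genes,
             n_positive_tissues = as.integer(object$positive_counts[genes]),
             flagged = genes %in% object$flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Heatmap of a tissue screen
#'
#' Base-graphics heatmap of the per-(gene, tissue) Spearman correlations,
#' genes in clustering leaf order, masked cells (p above alpha) in gray.
#'
#' @param x a `tissue_screen`.
#' @param ... passed to [graphics::image].
#' @return Invisibly, the plotted rho matrix.
#' @export
plot.tissue_screen <- function(x, ...) {
  res <- x$results
  genes <- x$gene_order
  tissues <- unique(res$tissue)
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(res$gene, genes), match(res$tissue, tissues))] <- res$rho
  msk <- matrix(TRUE, length(genes), length(tissues))
  msk[cbind(match(res$gene, genes), match(res$tissue, tissues))] <- res$masked
  disp <- m
  disp[msk] <- NA
  old <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(seq_along(tissues), seq_along(genes), t(disp[rev(seq_along(genes)), , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), xlab = "", ylab = "",
                  axes = FALSE, ...)
  graphics::axis(1, seq_along(tissues), tissues, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(genes), rev(genes), las = 2, cex.axis = 0.7)
  invisible(m)
}
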