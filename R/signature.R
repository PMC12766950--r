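#' Counts-per-10k log1p normalization
#'
#' Scales each cell (column) to 10,000 total counts, then applies `log1p`.
#' Cells with zero total counts are left at zero.
#'
#' @param counts genes x cells numeric matrix.
#' @return Matrix of the same shape.
#' @export
cp10k_log1p <- function(counts) {
  totals <- colSums(counts)
  totals[totals == 0] <- 1
  log1p(sweep(counts, 2, totals, "/") * 1e4)
}

#' Rank-sum differential expression between two genotypes
#'
#' Stand-in DE engine for signature derivation: counts are normalized to
#' counts-per-10k, per-gene fold changes are
#' `log2((mean_a + c) / (mean_b + c))` on the CP10K scale with pseudocount
#' `c = 1e-9`, and p-values come from the two-sided rank-sum test
#' ([rank_sum_test]) on `log1p` CP10K values, adjusted with
#' [adjust_pvalues]. A hurdle-model DE table produced externally can be
#' injected instead via [read_deg_table].
#'
#' @param sc a [single_cell_counts].
#' @param genotype_a,genotype_b genotype labels; fold change is a over b.
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @param pseudocount stability constant added to both CP10K means.
#' @return A `deg_table` data.frame: `gene_id`, `log2_fold_change`,
#'   `p_value`, `adj_p`, `direction`.
#' @export
differential_expression <- function(sc, genotype_a, genotype_b,
                                    adjust_method = "bonferroni",
                                    pseudocount = 1e-9) {
  stopifnot(inherits(sc, "single_cell_counts"))
  in_a <- sc$cell_genotype == genotype_a
  in_b <- sc$cell_genotype == genotype_b
  for (g in c(genotype_a, genotype_b))
    if (!any(sc$cell_genotype == g)) stop("genotype absent: ", g)
  if (sum(in_a) < 20 || sum(in_b) < 20)
    warning("fewer than 20 cells in a genotype; DE results will be unstable")
  if (nrow(sc$counts) < 2L) stop("need at least 2 genes")
  norm <- cp10k_log1p(sc$counts)
  cp10k <- expm1(norm)
  mean_a <- rowMeans(cp10k[, in_a, drop = FALSE])
  mean_b <- rowMeans(cp10k[, in_b, drop = FALSE])
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  pvals <- vapply(seq_len(nrow(norm)), function(i) {
    xa <- norm[i, in_a]; xb <- norm[i, in_b]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
    rank_sum_test(xa, xb, alternative = "two.sided")$p.value
  }, numeric(1))
  out <- data.frame(gene_id = rownames(sc$counts),
                    log2_fold_change = lfc,
                    p_value = pvals,
                    adj_p = adjust_pvalues(pvals, adjust_method),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Threshold a differential-expression table
#'
#' Selects genes with `adj_p` strictly below `adj_p_max` and fold change
#' strictly above `lfc_min` (in the stated direction). Both inequalities are
#' strict: a gene at `adj_p` exactly 0.01 is excluded.
#'
#' @param tbl a `deg_table`.
#' @param adj_p_max adjusted p-value ceiling (exclusive), default 0.01.
#' @param lfc_min log2 fold-change floor (exclusive), default 1.
#' @param direction `"up"` (default) keeps `log2_fold_change > lfc_min`;
#'   `"down"` keeps `log2_fold_change < -lfc_min`.
#' @return Character vector of selected gene ids (input order).
#' @export
select_degs <- function(tbl, adj_p_max = 0.01, lfc_min = 1,
                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nrow(tbl) == 0L) return(character(0))
  keep <- tbl$adj_p < adj_p_max &
    (if (direction == "up") tbl$log2_fold_change > lfc_min
     else tbl$log2_fold_change < -lfc_min)
  tbl$gene_id[keep]
}

#' Map gene identifiers through an ortholog table
#'
#' Unmapped genes are dropped and reported; duplicate targets after mapping
#' are collapsed to one occurrence (first appearance order).
#'
#' @param genes character vector of source-species gene ids.
#' @param ortholog_map named character vector (see [read_ortholog_map]).
#' @return List with `mapped` (unique target ids, order of first appearance)
#'   and `unmapped` (source ids without a map entry).
#' @export
map_orthologs <- function(genes, ortholog_map) {
  genes <- as.character(genes)
  hit <- genes %in% names(ortholog_map)
  mapped <- unique(unname(ortholog_map[genes[hit]]))
  list(mapped = mapped, unmapped = genes[!hit])
}

#' Intersect mapped genes with a hallmark gene set
#'
#' Final stage of signature derivation: the signature is the intersection of
#' the ortholog-mapped differentially expressed genes with a curated
#' pathway-up gene set, ordered as in the hallmark set. Filter-stage counts
#' are recorded as provenance.
#'
#' @param mapped character vector of mapped gene ids.
#' @param hallmark a [gene_set].
#' @param n_degs,n_mapped optional provenance counts from earlier stages
#'   (default to `length(mapped)` when the earlier stages are not recorded).
#' @return An object of class `signature_result`: `genes` (ordered ids) and
#'   `provenance` (named counts: n_degs, n_mapped, n_hallmark,
#'   n_intersected).
#' @export
intersect_signature <- function(mapped, hallmark, n_degs = NULL,
                                n_mapped = NULL) {
  stopifnot(inherits(hallmark, "gene_set"))
  mapped <- as.character(mapped)
  genes <- hallmark$members[hallmark$members %in% mapped]
  if (length(genes) == 0L)
    warning("empty signature: no overlap between mapped genes and '",
            hallmark$name, "'")
  prov <- c(n_degs = as.integer(if (is.null(n_degs)) length(mapped)
                                else n_degs),
            n_mapped = as.integer(if (is.null(n_mapped)) length(mapped)
                                  else n_mapped),
            n_hallmark = length(hallmark$members),
            n_intersected = length(genes))
  structure(list(genes = genes, provenance = prov, hallmark = hallmark$name),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("signature_result:", length(x$genes), "genes",
      sprintf("(DEGs %d -> mapped %d -> intersect '%s' [%d] -> %d)\n",
              x$provenance[["n_degs"]], x$provenance[["n_mapped"]],
              x$hallmark, x$provenance[["n_hallmark"]],
              x$provenance[["n_intersected"]]))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Derive a signature end to end
#'
#' Convenience wrapper chaining [differential_expression] (or an injected
#' `deg_table`), [select_degs], [map_orthologs] and [intersect_signature].
#'
#' @param sc a [single_cell_counts], or `NULL` when `deg_table` is given.
#' @param genotype_a,genotype_b genotype labels (a is the activated state).
#' @param ortholog_map named character vector.
#' @param hallmark a [gene_set] of target-species symbols.
#' @param deg_table optional externally produced `deg_table`.
#' @param adj_p_max,lfc_min selection thresholds (strict), defaults 0.01 / 1.
#' @param adjust_method multiplicity correction for the built-in DE stage.
#' @return A `signature_result` with full provenance.
#' @export
derive_signature <- function(sc = NULL, genotype_a, genotype_b, ortholog_map,
                             hallmark, deg_table = NULL, adj_p_max = 0.01,
                             lfc_min = 1, adjust_method = "bonferroni") {
  tbl <- if (!is.null(deg_table)) deg_table
  else differential_expression(sc, genotype_a, genotype_b,
                               adjust_method = adjust_method)
  degs <- select_degs(tbl, adj_p_max = adj_p_max, lfc_min = lfc_min,
                      direction = "up")
  mp <- map_orthologs(degs, ortholog_map)
  intersect_signature(mp$mapped, hallmark, n_degs = length(degs),
                      n_mapped = length(mp$mapped))
}

#' Write a signature as a single-column TSV and one-line GMT
#'
#' @param sig a `signature_result`.
#' @param path_tsv,path_gmt output paths (either may be `NULL` to skip).
#' @param name set name used in the GMT line.
#' @return Invisibly, `sig`.
#' @export
write_signature <- function(sig, path_tsv = NULL, path_gmt = NULL,
                            name = "SIGNATURE") {
  stopifnot(inherits(sig, "signature_result"))
  if (!is.null(path_tsv))
    utils::write.table(data.frame(gene_id = sig$genes), path_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_gmt))
    write_gmt(list(gene_set(name, sig$genes)), path_gmt)
  invisible(sig)
}
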