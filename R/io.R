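#' @importFrom utils read.delim write.table head tail
NULL

# delimiter from extension (.csv -> comma, anything else tab), overridable
.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

.check_unique <- function(ids, what) {
  if (anyDuplicated(ids))
    stop("duplicate ", what, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(ids)
}

#' Expression matrix with tissue annotation
#'
#' Container for a genes x samples matrix of continuous expression values on a
#' log2(TPM + 1)-like scale, together with a sample-to-tissue map. Values must
#' be finite and non-negative; gene and sample identifiers unique; every
#' sample annotated with a tissue.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param sample_tissue named character vector mapping sample id to tissue.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_tissue) {
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- rownames(values); samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("values must have gene row names and sample column names")
  .check_unique(genes, "gene identifiers")
  .check_unique(samples, "sample identifiers")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  missing <- setdiff(samples, names(sample_tissue))
  if (length(missing))
    stop("samples missing a tissue label: ", paste(missing, collapse = ", "))
  st <- as.character(sample_tissue[samples])
  if (any(is.na(st) | st == "")) stop("empty tissue labels")
  names(st) <- samples
  structure(list(values = values, sample_tissue = st),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples,", length(unique(x$sample_tissue)), "tissues\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Unsigned gene set
#'
#' @param name set label.
#' @param members character vector of gene identifiers (non-empty; duplicates
#'   are dropped with a warning).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- as.character(members)
  if (length(members) == 0L) stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "' has duplicate members; deduplicated")
    members <- unique(members)
  }
  structure(list(name = name, members = members), class = "gene_set")
}

#' Signed gene set
#'
#' A gene set whose members carry signed real weights (for example pathway
#' footprints with genes weighted both positively and negatively).
#'
#' @param name set label.
#' @param weights named numeric vector, names are gene identifiers; weights
#'   finite and nonzero, genes unique.
#' @return An object of class `signed_gene_set`.
#' @export
signed_gene_set <- function(name, weights) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by gene identifier")
  .check_unique(names(weights), "gene identifiers in signed set")
  if (any(!is.finite(weights)) || any(weights == 0))
    stop("weights must be finite and nonzero")
  structure(list(name = name, weights = weights), class = "signed_gene_set")
}

#' Single-cell UMI count container
#'
#' Genes x cells matrix of non-negative integer UMI counts with per-cell
#' genotype and cluster labels.
#'
#' @param counts numeric matrix of integers, genes in rows, cells in columns,
#'   with dimnames.
#' @param cell_genotype,cell_cluster named character vectors over cell ids.
#' @return An object of class `single_cell_counts`.
#' @export
single_cell_counts <- function(counts, cell_genotype, cell_cluster) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  genes <- rownames(counts); cells <- colnames(counts)
  if (is.null(genes) || is.null(cells))
    stop("counts must have gene row names and cell column names")
  .check_unique(genes, "gene identifiers")
  .check_unique(cells, "cell identifiers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"   # uniform storage across input routes
  for (nm in c("cell_genotype", "cell_cluster")) {
    v <- get(nm)
    missing <- setdiff(cells, names(v))
    if (length(missing))
      stop("cells missing ", sub("cell_", "", nm), " labels: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(counts = counts,
                 cell_genotype = as.character(cell_genotype[cells]),
                 cell_cluster = as.character(cell_cluster[cells])),
            class = "single_cell_counts")
}

#' @export
print.single_cell_counts <- function(x, ...) {
  cat("single_cell_counts:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", "genotypes:",
      paste(names(table(x$cell_genotype)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a delimited expression matrix with sample metadata
#'
#' The matrix file has genes in rows (first column gene identifier) and a
#' header row of sample identifiers; the metadata file has columns
#' `sample_id` and `tissue`. Samples present in the matrix but absent from
#' the metadata are an error. Delimiters are auto-detected from the file
#' extension (`.csv` comma, otherwise tab) and can be overridden.
#'
#' @param path_matrix,path_metadata file paths.
#' @param sep optional delimiter override applied to both files.
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path_matrix, path_metadata, sep = NULL) {
  dm <- utils::read.delim(path_matrix, sep = .sep_for(path_matrix, sep),
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(dm) < 2L) stop("matrix file needs a gene column and >= 1 sample")
  genes <- as.character(dm[[1L]])
  .check_unique(genes, "gene identifiers")
  vals <- as.matrix(dm[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cells")
  rownames(vals) <- genes
  meta <- utils::read.delim(path_metadata, sep = .sep_for(path_metadata, sep),
                            header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(meta)))
    stop("metadata must have columns sample_id and tissue")
  st <- stats::setNames(as.character(meta$tissue), meta$sample_id)
  expression_matrix(vals, st)
}

#' Write an expression matrix and its sample metadata
#'
#' @param em an [expression_matrix].
#' @param path_matrix,path_metadata output paths; delimiter from extension.
#' @param sep optional delimiter override.
#' @return Invisibly, `em`.
#' @export
write_expression_matrix <- function(em, path_matrix, path_metadata,
                                    sep = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  s <- .sep_for(path_matrix, sep)
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_matrix, sep = s, quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(em$sample_tissue),
                     tissue = em$sample_tissue, stringsAsFactors = FALSE)
  utils::write.table(meta, path_metadata,
                     sep = .sep_for(path_metadata, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(em)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then members. The
#' description field is discarded; line order is preserved; duplicate members
#' within a line are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return A list of [gene_set] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    out[[i]] <- gene_set(f[1L], f[-c(1L, 2L)])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, "na", s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read signed gene sets from a 3-column TSV
#'
#' Columns `set`, `gene`, `weight`; one [signed_gene_set] per distinct set, in
#' order of first appearance.
#'
#' @param path TSV path.
#' @return List of [signed_gene_set].
#' @export
read_signed_sets <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("set", "gene", "weight") %in% names(df)))
    stop("signed set file must have columns set, gene, weight")
  lapply(unique(df$set), function(s) {
    sub <- df[df$set == s, , drop = FALSE]
    signed_gene_set(s, stats::setNames(as.numeric(sub$weight), sub$gene))
  })
}

#' Read single-cell UMI counts
#'
#' Accepts either a MatrixMarket triplet file (with `features.tsv` and
#' `barcodes.tsv` companions in the same directory, overridable) or a dense
#' delimited file with genes in rows and a header of cell identifiers. The
#' cell metadata file has columns `cell_id`, `genotype`, `cluster`. MTX
#' indices are 1-based per the MatrixMarket standard.
#'
#' @param path counts file (`.mtx` triplet or dense `.csv`/`.tsv`).
#' @param path_cell_meta cell metadata path.
#' @param path_features,path_barcodes companion paths for MTX input; default
#'   `features.tsv` / `barcodes.tsv` next to the matrix.
#' @param sep optional delimiter override for dense input.
#' @return A [single_cell_counts].
#' @export
read_sc_counts <- function(path, path_cell_meta,
                           path_features = NULL, path_barcodes = NULL,
                           sep = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(path_features))
      path_features <- file.path(dirname(path), "features.tsv")
    if (is.null(path_barcodes))
      path_barcodes <- file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(path_features, warn = FALSE)
    genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
    cells <- readLines(path_barcodes, warn = FALSE)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("MTX dimensions disagree with features/barcodes files")
    dimnames(m) <- list(genes, cells)
  } else {
    dm <- utils::read.delim(path, sep = .sep_for(path, sep), header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(dm[[1L]])
    m <- as.matrix(dm[, -1L, drop = FALSE])
    rownames(m) <- genes
  }
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(m != round(m))) stop("fractional counts are not valid UMI data")
  meta <- utils::read.delim(path_cell_meta, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("cell_id", "genotype", "cluster") %in% names(meta)))
    stop("cell metadata must have columns cell_id, genotype, cluster")
  single_cell_counts(m,
                     stats::setNames(meta$genotype, meta$cell_id),
                     stats::setNames(meta$cluster, meta$cell_id))
}

#' Write single-cell counts as an MTX triplet plus cell metadata
#'
#' @param sc a [single_cell_counts].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `cells.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_sc_counts <- function(sc, dir) {
  stopifnot(inherits(sc, "single_cell_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(sc$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sc$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sc$counts), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(cell_id = colnames(sc$counts),
                     genotype = sc$cell_genotype,
                     cluster = sc$cell_cluster, stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a two-column ortholog map
#'
#' Columns `source` and `target` (header optional if exactly two unnamed
#' columns). Source identifiers must be unique; targets non-empty.
#'
#' @param path TSV path.
#' @return Named character vector: `map["sourceGene"] == "TARGETGENE"`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          header = TRUE)
  if (ncol(df) < 2L) stop("ortholog map needs two columns")
  src <- as.character(df[[1L]]); tgt <- as.character(df[[2L]])
  .check_unique(src, "source gene identifiers")
  if (any(!nzchar(tgt))) stop("empty target identifiers")
  stats::setNames(tgt, src)
}

#' Read per-cell ISH dot observations
#'
#' TSV with columns `cell_id`, `condition`, `dots`, `cluster_fraction`.
#' Dots must be non-negative integers, cluster fractions in `[0, 1]`, and a
#' cell with zero dots must have cluster fraction 0.
#'
#' @param path TSV path.
#' @return A data.frame of validated observations.
#' @export
read_ish_observations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "dots", "cluster_fraction")
  if (!all(need %in% names(df)))
    stop("ISH file must have columns ", paste(need, collapse = ", "))
  validate_ish_observations(df)
}

#' Validate ISH observations
#'
#' @param df data.frame with `cell_id`, `condition`, `dots`,
#'   `cluster_fraction`.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_ish_observations <- function(df) {
  if (any(df$dots < 0) || any(df$dots != round(df$dots)))
    stop("dots must be non-negative integers")
  if (any(df$cluster_fraction < 0) || any(df$cluster_fraction > 1))
    stop("cluster_fraction must lie in [0, 1]")
  if (any(df$dots == 0 & df$cluster_fraction != 0))
    stop("cells with zero dots must have cluster_fraction 0")
  df
}

#' Read an externally produced differential-expression table
#'
#' TSV with columns `gene_id`, `log2_fold_change`, `p_value`, `adj_p`; allows
#' injecting output of an external DE engine (e.g. a hurdle-model test) into
#' the signature derivation in place of the built-in rank-sum stand-in.
#'
#' @param path TSV path.
#' @return A `deg_table` data.frame (see [differential_expression]).
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fold_change", "p_value", "adj_p")
  if (!all(need %in% names(df)))
    stop("DEG table must have columns ", paste(need, collapse = ", "))
  if (any(df$adj_p + 1e-12 < df$p_value))
    stop("adjusted p-values must not be smaller than raw p-values")
  df$direction <- ifelse(df$log2_fold_change >= 0, "up", "down")
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Write a differential-expression table
#'
#' @param tbl a `deg_table`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(tbl, path) {
  utils::write.table(tbl[, c("gene_id", "log2_fold_change", "p_value",
                             "adj_p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
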