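#' @importFrom stats rnorm rpois rnbinom runif rbinom qnbinom pnbinom setNames
NULL

#' Configuration for the cell-line screen simulator
#'
#' Defines a synthetic pan-cancer cell-line panel: `n_tissues` tissues with
#' `lines_per_tissue` cell lines each, one target gene, `n_signature_genes`
#' signature genes and `n_null_genes` null genes. In a fraction
#' `planted_tissue_fraction` of tissues, every signature gene is coupled to
#' the target through a Gaussian copula with latent correlation
#' `planted_rho`, so the planted rank correlation is the copula-implied
#' Spearman value `(6 / pi) * asin(planted_rho / 2)`; null genes are
#' independent of the target everywhere.
#'
#' @param n_tissues number of tissues (default 22, a typical panel breadth).
#' @param lines_per_tissue cell lines per tissue; at least 4 so quartiles are
#'   non-empty.
#' @param n_signature_genes,n_null_genes gene counts.
#' @param planted_rho latent copula correlation in (-1, 1).
#' @param planted_tissue_fraction fraction of tissues carrying the planted
#'   correlation, in \[0, 1\].
#' @param noise_sd lognormal scale of expression variation (log-TPM units).
#' @param seed integer RNG seed (mandatory; generators are fully seeded).
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_tissues = 22, lines_per_tissue = 30,
                              n_signature_genes = 10, n_null_genes = 100,
                              planted_rho = 0.6,
                              planted_tissue_fraction = 6 / 22,
                              noise_sd = 1, seed) {
  stopifnot(n_tissues >= 1, n_signature_genes >= 0, n_null_genes >= 0,
            noise_sd > 0)
  if (lines_per_tissue < 4)
    stop("lines_per_tissue must be at least 4 (quartiles must be non-empty)")
  if (abs(planted_rho) >= 1) stop("planted_rho must lie in (-1, 1)")
  if (planted_tissue_fraction < 0 || planted_tissue_fraction > 1)
    stop("planted_tissue_fraction must lie in [0, 1]")
  if (missing(seed)) stop("seed is mandatory")
  structure(list(n_tissues = n_tissues, lines_per_tissue = lines_per_tissue,
                 n_signature_genes = n_signature_genes,
                 n_null_genes = n_null_genes, planted_rho = planted_rho,
                 planted_tissue_fraction = planted_tissue_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Spearman correlation implied by a Gaussian copula
#'
#' For bivariate normal latents with correlation `rho`, the population
#' Spearman correlation of any strictly monotone transforms is
#' `(6 / pi) * asin(rho / 2)`.
#'
#' @param rho latent (Pearson) correlation.
#' @return Implied Spearman correlation.
#' @export
copula_implied_spearman <- function(rho) (6 / pi) * asin(rho / 2)

#' Simulate a tissue-annotated cell-line expression matrix
#'
#' Draws latent standard normals per sample; signature genes in planted
#' tissues share a copula with the target gene at latent correlation
#' `planted_rho`. Latents are mapped to a non-negative log2(TPM + 1)-like
#' scale through the strictly monotone transform
#' `log2(1 + exp(mu_g + noise_sd * z))`, which preserves all rank
#' correlations. The first `round(planted_tissue_fraction * n_tissues)`
#' tissues are the planted ones.
#'
#' @param cfg a [screen_sim_config].
#' @param target_gene name of the target gene column (default `"WNT7B"`).
#' @return A list with `em` (an [expression_matrix]), `truth` (data.frame of
#'   gene, tissue, planted flag) and `implied_spearman` (scalar).
#' @export
simulate_cell_line_matrix <- function(cfg, target_gene = "WNT7B") {
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(cfg$seed)
  n_t <- cfg$n_tissues; n_l <- cfg$lines_per_tissue
  tissues <- sprintf("tissue%02d", seq_len(n_t))
  n_planted_tissues <- round(cfg$planted_tissue_fraction * n_t)
  planted_tissues <- tissues[seq_len(n_planted_tissues)]
  sig_genes <- if (cfg$n_signature_genes > 0)
    sprintf("SIG%03d", seq_len(cfg$n_signature_genes)) else character(0)
  null_genes <- if (cfg$n_null_genes > 0)
    sprintf("NUL%04d", seq_len(cfg$n_null_genes)) else character(0)
  genes <- c(target_gene, sig_genes, null_genes)
  rho <- cfg$planted_rho

  # gene-specific lognormal location so genes differ in baseline abundance
  mu <- stats::rnorm(length(genes), mean = 2, sd = 1)
  names(mu) <- genes

  cols <- vector("list", n_t)
  sample_tissue <- character(0)
  for (ti in seq_len(n_t)) {
    z_target <- stats::rnorm(n_l)
    z <- matrix(stats::rnorm(n_l * length(genes)), nrow = n_l,
                dimnames = list(NULL, genes))
    z[, target_gene] <- z_target
    if (tissues[ti] %in% planted_tissues && length(sig_genes)) {
      eps <- matrix(stats::rnorm(n_l * length(sig_genes)), nrow = n_l)
      z[, sig_genes] <- rho * z_target + sqrt(1 - rho^2) * eps
    }
    vals <- t(log2(1 + exp(sweep(z * cfg$noise_sd, 2, mu[colnames(z)], "+"))))
    ids <- sprintf("%s_L%03d", tissues[ti], seq_len(n_l))
    colnames(vals) <- ids
    cols[[ti]] <- vals
    sample_tissue <- c(sample_tissue,
                       stats::setNames(rep(tissues[ti], n_l), ids))
  }
  values <- do.call(cbind, cols)
  em <- expression_matrix(values, sample_tissue)
  truth <- expand.grid(gene = c(sig_genes, null_genes), tissue = tissues,
                       stringsAsFactors = FALSE)
  truth$planted <- truth$gene %in% sig_genes & truth$tissue %in% planted_tissues
  list(em = em, truth = truth,
       implied_spearman = copula_implied_spearman(rho),
       planted_genes = sig_genes, planted_tissues = planted_tissues,
       null_genes = null_genes, target_gene = target_gene)
}

#' Configuration for the single-cell count simulator
#'
#' Emulates a genotyped single-nucleus experiment: per genotype,
#' `n_cells_per_genotype` cells are assigned to clusters by
#' `cluster_proportions`; all genes are drawn from a negative binomial with
#' gene-specific means and common `dispersion` (NB size); the target gene's
#' zero/non-zero status is planted per (genotype, cluster) through
#' `expressing_fraction`; and the designated pathway gene set has its means
#' multiplied by `exp(pathway_gene_shift[genotype])`.
#'
#' Synthetic gene symbols are mouse-cased (e.g. `Pw001`, target `Wnt7b`) so
#' that downstream ortholog mapping to upper-case human symbols is exercised
#' nontrivially.
#'
#' @param n_cells_per_genotype cells per genotype.
#' @param n_genes total genes including the target and pathway genes.
#' @param n_pathway_genes size of the designated pathway set.
#' @param cluster_proportions named list, one simplex vector per genotype
#'   (named by cluster).
#' @param expressing_fraction named list per genotype of named per-cluster
#'   fractions in \[0, 1\] for the target gene.
#' @param pathway_gene_shift named numeric per genotype: natural-log fold
#'   shift applied to pathway gene means.
#' @param dispersion negative-binomial size parameter (> 0); smaller is more
#'   overdispersed.
#' @param target_gene synthetic mouse-style target symbol.
#' @param seed integer RNG seed (mandatory).
#' @return An object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells_per_genotype = 1000, n_genes = 200,
                          n_pathway_genes = 50,
                          cluster_proportions = list(
                            RZ = c(Pit = 0.5, Neck = 0.5),
                            RZK = c(Pit = 0.5, Neck = 0.5)),
                          expressing_fraction = list(
                            RZ = c(Pit = 0.1, Neck = 0.1),
                            RZK = c(Pit = 0.4, Neck = 0.4)),
                          pathway_gene_shift = c(RZ = 0, RZK = log(2)),
                          dispersion = 2, target_gene = "Wnt7b", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells_per_genotype >= 1, n_genes >= 2, dispersion > 0,
            n_pathway_genes >= 0, n_pathway_genes <= n_genes - 1)
  genotypes <- names(cluster_proportions)
  if (is.null(genotypes) || !setequal(genotypes, names(expressing_fraction)))
    stop("cluster_proportions and expressing_fraction must share genotype names")
  if (!all(genotypes %in% names(pathway_gene_shift)))
    stop("pathway_gene_shift must name every genotype")
  for (g in genotypes) {
    p <- cluster_proportions[[g]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("cluster_proportions for ", g, " must be a simplex vector")
    ef <- expressing_fraction[[g]]
    if (!all(names(p) %in% names(ef)))
      stop("expressing_fraction for ", g, " must cover every cluster")
    if (any(ef < 0 | ef > 1))
      stop("expressing fractions must lie in [0, 1]")
  }
  structure(list(n_cells_per_genotype = n_cells_per_genotype,
                 n_genes = n_genes, n_pathway_genes = n_pathway_genes,
                 cluster_proportions = cluster_proportions,
                 expressing_fraction = expressing_fraction,
                 pathway_gene_shift = pathway_gene_shift,
                 dispersion = dispersion, target_gene = target_gene,
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

# NB draw conditioned on being >= 1, via the quantile transform
.rnbinom_truncated <- function(n, mu, size) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Simulate genotyped single-cell UMI counts with planted effects
#'
#' @param cfg an [sc_sim_config].
#' @return A list with `sc` (a [single_cell_counts]) and `truth` (the planted
#'   expressing fractions, pathway gene ids and shifts).
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  genotypes <- names(cfg$cluster_proportions)
  n_bg <- cfg$n_genes - 1L - cfg$n_pathway_genes
  pw_genes <- if (cfg$n_pathway_genes > 0)
    sprintf("Pw%03d", seq_len(cfg$n_pathway_genes)) else character(0)
  bg_genes <- if (n_bg > 0) sprintf("Bg%04d", seq_len(n_bg)) else character(0)
  genes <- c(cfg$target_gene, pw_genes, bg_genes)
  base_mu <- exp(stats::rnorm(length(genes), mean = 0, sd = 1))
  names(base_mu) <- genes

  blocks <- list(); genos <- character(0); clusters <- character(0)
  for (g in genotypes) {
    n <- cfg$n_cells_per_genotype
    props <- cfg$cluster_proportions[[g]]
    cl <- sample(names(props), n, replace = TRUE, prob = props)
    # guard against a cluster with nominal mass dropping out entirely
    empty <- setdiff(names(props)[props > 0], unique(cl))
    while (length(empty)) {
      warning("empty cluster after sampling for genotype ", g,
              "; resampling")
      cl <- sample(names(props), n, replace = TRUE, prob = props)
      empty <- setdiff(names(props)[props > 0], unique(cl))
    }
    mu_g <- base_mu
    if (length(pw_genes))
      mu_g[pw_genes] <- mu_g[pw_genes] * exp(cfg$pathway_gene_shift[[g]])
    cnt <- matrix(0, nrow = length(genes), ncol = n,
                  dimnames = list(genes, NULL))
    for (j in seq_along(genes)) {
      gene <- genes[j]
      if (gene == cfg$target_gene) next
      cnt[j, ] <- stats::rnbinom(n, mu = mu_g[gene], size = cfg$dispersion)
    }
    # target gene: plant the expressing fraction per cluster exactly
    ef <- cfg$expressing_fraction[[g]]
    expressing <- stats::runif(n) < ef[cl]
    tg <- numeric(n)
    if (any(expressing))
      tg[expressing] <- .rnbinom_truncated(sum(expressing),
                                           mu = base_mu[cfg$target_gene] + 1,
                                           size = cfg$dispersion)
    cnt[cfg$target_gene, ] <- tg
    blocks[[g]] <- cnt
    genos <- c(genos, rep(g, n))
    clusters <- c(clusters, cl)
  }
  counts <- do.call(cbind, blocks)
  cells <- sprintf("cell%05d", seq_len(ncol(counts)))
  colnames(counts) <- cells
  sc <- single_cell_counts(counts,
                           stats::setNames(genos, cells),
                           stats::setNames(clusters, cells))
  list(sc = sc,
       truth = list(expressing_fraction = cfg$expressing_fraction,
                    pathway_genes = pw_genes,
                    pathway_gene_shift = cfg$pathway_gene_shift,
                    target_gene = cfg$target_gene))
}

#' Configuration for the ISH dot-count simulator
#'
#' Per condition, cells carry Poisson-distributed dot counts with mean
#' `dot_rate[condition]`; a cell with at least one dot has a clustered-dot
#' fraction drawn above 0.10 with probability `cluster_prob[condition]`
#' (uniform on (0.10, 0.60\]) and below it otherwise (uniform on \[0, 0.10\]).
#'
#' @param n_cells cells per condition.
#' @param dot_rate named positive numeric, mean dots per cell per condition.
#' @param cluster_prob named numeric in \[0, 1\] per condition.
#' @param seed integer RNG seed (mandatory).
#' @return An object of class `ish_sim_config`.
#' @export
ish_sim_config <- function(n_cells = 200,
                           dot_rate = c(CTRL = 0.5, RZ = 2, RZK = 12),
                           cluster_prob = c(CTRL = 0, RZ = 0.05, RZK = 0.5),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells >= 1, all(dot_rate > 0))
  if (is.null(names(dot_rate)) || !setequal(names(dot_rate),
                                            names(cluster_prob)))
    stop("dot_rate and cluster_prob must share condition names")
  if (any(cluster_prob < 0 | cluster_prob > 1))
    stop("cluster_prob must lie in [0, 1]")
  structure(list(n_cells = n_cells, dot_rate = dot_rate,
                 cluster_prob = cluster_prob, seed = as.integer(seed)),
            class = "ish_sim_config")
}

#' Simulate per-cell ISH dot observations
#'
#' @param cfg an [ish_sim_config].
#' @return A list with `obs` (data.frame: cell_id, condition, dots,
#'   cluster_fraction) and `truth` (the configured rates).
#' @export
simulate_ish <- function(cfg) {
  stopifnot(inherits(cfg, "ish_sim_config"))
  set.seed(cfg$seed)
  conditions <- names(cfg$dot_rate)
  rows <- lapply(conditions, function(cond) {
    dots <- stats::rpois(cfg$n_cells, cfg$dot_rate[[cond]])
    clustered <- stats::runif(cfg$n_cells) < cfg$cluster_prob[[cond]]
    frac <- ifelse(clustered, stats::runif(cfg$n_cells, 0.10, 0.60),
                   stats::runif(cfg$n_cells, 0, 0.10))
    frac[dots == 0] <- 0
    data.frame(cell_id = sprintf("%s_c%04d", cond, seq_len(cfg$n_cells)),
               condition = cond, dots = dots, cluster_fraction = frac,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  list(obs = validate_ish_observations(obs),
       truth = list(dot_rate = cfg$dot_rate,
                    cluster_prob = cfg$cluster_prob))
}

#' Synthetic ortholog map for mouse-cased symbols
#'
#' Maps each synthetic mouse-style symbol (e.g. `Pw001`) to its upper-case
#' human-style counterpart (`PW001`), emulating mouse-to-human ortholog
#' conversion for generator output.
#'
#' @param genes character vector of mouse-style symbols.
#' @return Named character vector usable with [map_orthologs].
#' @export
synthetic_ortholog_map <- function(genes) {
  stats::setNames(toupper(genes), genes)
}
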