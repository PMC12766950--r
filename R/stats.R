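#' @useDynLib kraswnt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dhyper pnorm pt r2dtable
NULL

# p-values live in (0, 1]: clamp the numerical underflow end, never the top.
.clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

.match_alternative <- function(alternative) {
  match.arg(alternative, c("two.sided", "greater", "less"))
}

#' Construct a test result
#'
#' Light container for the outcome of one hypothesis test. Inherits from
#' `htest` so base R's print method applies.
#'
#' @param statistic named numeric scalar, the test statistic.
#' @param p_value p-value in (0, 1].
#' @param alternative one of `"two.sided"`, `"greater"`, `"less"`.
#' @param method character label for the procedure.
#' @param effect_size optional named effect size (e.g. an odds ratio).
#' @param data_name description of the data the test was run on.
#' @return An object of class `c("test_result", "htest")`.
#' @export
test_result <- function(statistic, p_value, alternative, method,
                        effect_size = NULL, data_name = "data") {
  stopifnot(length(p_value) == 1L, is.finite(p_value))
  p_value <- .clamp_p(p_value)
  if (!is.null(effect_size) && is.null(names(effect_size)))
    names(effect_size) <- "effect size"
  out <- list(statistic = statistic, p.value = p_value,
              alternative = alternative, method = method,
              estimate = effect_size, data.name = data_name)
  class(out) <- c("test_result", "htest")
  out
}

.stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("kraswnt_undefined_error", "error",
                                     "condition")))
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties. The p-value comes from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` for `n > 10`, and
#' from exact enumeration of all `n!` rank permutations for `n <= 10`
#' (enumeration ignores tie multiplicity; ties are ranked by average rank and
#' the tied rank vector is permuted as-is).
#'
#' A constant input vector leaves the correlation undefined; this is signalled
#' with a classed error (`kraswnt_undefined_error`) rather than returning NaN.
#'
#' @param x,y numeric vectors of equal length (at least 3), finite.
#' @param alternative alternative hypothesis for the correlation.
#' @param exact logical; force or forbid exact enumeration. Default `NULL`
#'   selects exact for `n <= 10`.
#' @return A [test_result] with `statistic = rho`.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))$statistic
#' @export
spearman_test <- function(x, y, alternative = "two.sided", exact = NULL) {
  alternative <- .match_alternative(alternative)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    .stop_undefined("Spearman correlation undefined for a constant vector")

  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= 10L
  if (exact && n > 10L)
    stop("exact enumeration only available for n <= 10")

  if (exact) {
    s_obs <- sum(rx * ry)
    center <- n * mean(rx) * mean(ry)
    cnt <- .spearman_perm_counts(rx, ry, s_obs, center)
    p <- switch(alternative,
                greater   = cnt[1] / cnt[4],
                less      = cnt[2] / cnt[4],
                two.sided = cnt[3] / cnt[4])
    method <- "Spearman rank correlation (exact permutation null)"
  } else {
    if (abs(rho) >= 1) {
      tstat <- sign(rho) * Inf
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    }
    pg <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    pl <- stats::pt(tstat, df = n - 2, lower.tail = TRUE)
    p <- switch(alternative,
                greater   = pg,
                less      = pl,
                two.sided = min(1, 2 * min(pg, pl)))
    method <- "Spearman rank correlation (t approximation)"
  }
  test_result(c(rho = rho), p, alternative, method,
              data_name = paste0("x and y (n = ", n, ")"))
}

# Exact null distribution of the rank sum of the first group: dynamic program
# over doubled pooled ranks (doubling makes average ranks integral), counting
# subsets of size n1 by sum. Returns P(W >= w), P(W <= w).
.rank_sum_exact_tails <- function(r_pooled, n1, w_obs) {
  r2 <- as.integer(round(2 * r_pooled))
  smax <- sum(r2)
  # dp[[k + 1]][s + 1] = number of size-k subsets with doubled-rank sum s
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(smax))
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(smax + 1L)
  for (v in r2) {
    for (k in seq(min(n1, length(r2)), 1L)) {
      shifted <- c(numeric(v), dp[[k]][seq_len(smax + 1L - v)])
      dp[[k + 1L]] <- dp[[k + 1L]] + shifted
    }
  }
  counts <- dp[[n1 + 1L]]
  total <- sum(counts)
  sums <- seq(0L, smax)
  w2 <- 2 * w_obs
  c(ge = sum(counts[sums >= w2 - 1e-9]) / total,
    le = sum(counts[sums <= w2 + 1e-9]) / total)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Default mode is the tie-uncorrected normal approximation on the rank sum of
#' `x`, with no continuity correction — matching the plain large-sample
#' rank-sum z statistic common in scientific Python toolchains, so that
#' results are comparable to pipelines built on it. An exact mode computes
#' the full permutation distribution of the rank sum by dynamic programming
#' over doubled pooled ranks (supported up to `length(x) + length(y) <= 30`,
#' ties included); the exact two-sided p-value is twice the smaller tail,
#' capped at 1.
#'
#' @param x,y numeric vectors, non-empty.
#' @param alternative `"greater"` means `x` stochastically larger than `y`.
#' @param exact logical, use exact enumeration.
#' @return A [test_result]; statistic `W` is the rank sum of `x` (z is also
#'   reported in the approximate mode).
#' @examples
#' rank_sum_test(c(3, 4, 5), c(1, 2), alternative = "greater", exact = TRUE)
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided", exact = FALSE) {
  alternative <- .match_alternative(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])

  if (exact) {
    if (n > 30L) stop("exact enumeration only available for n1 + n2 <= 30")
    tails <- .rank_sum_exact_tails(r, n1, w)
    p <- switch(alternative,
                greater   = tails[["ge"]],
                less      = tails[["le"]],
                two.sided = min(1, 2 * min(tails)))
    return(test_result(c(W = w), p, alternative,
                       "Wilcoxon rank-sum test (exact enumeration)",
                       data_name = paste0("x (n=", n1, ") vs y (n=", n2, ")")))
  }

  mu <- n1 * (n + 1) / 2
  sigma <- sqrt(n1 * n2 * (n + 1) / 12)
  z <- (w - mu) / sigma
  p <- switch(alternative,
              greater   = stats::pnorm(z, lower.tail = FALSE),
              less      = stats::pnorm(z, lower.tail = TRUE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  p <- min(p, 1)
  test_result(c(W = w, z = z), p, alternative,
              "Wilcoxon rank-sum test (normal approximation, no tie or continuity correction)",
              data_name = paste0("x (n=", n1, ") vs y (n=", n2, ")"))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests symmetry of `x` about `mu0`. Exact null for `n <= 20` (after
#' removing exact zeros) by enumerating all `2^n` sign assignments via subset
#' sums of the ranks of `|x - mu0|`; normal approximation (no tie or
#' continuity correction) otherwise. The exact two-sided p-value is twice the
#' smaller tail, capped at 1.
#'
#' @param x numeric vector; at least 5 non-zero deviations expected.
#' @param mu0 null location.
#' @param alternative `"greater"` means the location of `x` exceeds `mu0`.
#' @return A [test_result] with statistic `V`, the positive-deviation rank sum.
#' @examples
#' signed_rank_test(c(1.2, 0.8, 1.5, 2.1, 0.3), mu0 = 0,
#'                  alternative = "greater")
#' @export
signed_rank_test <- function(x, mu0 = 0, alternative = "two.sided") {
  alternative <- .match_alternative(alternative)
  stopifnot(is.numeric(x), all(is.finite(x)), is.finite(mu0))
  d <- x - mu0
  nzero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all observations equal mu0; test undefined")
  if (nzero > 0L)
    warning(nzero, " observation(s) equal to mu0 removed")
  if (n < 5L)
    warning("fewer than 5 non-zero deviations; p-value is coarse")
  ra <- rank(abs(d))
  v <- sum(ra[d > 0])

  if (n <= 20L) {
    # subset-sum enumeration over doubled ranks (2^n sign vectors)
    r2 <- as.integer(round(2 * ra))
    sums <- 0L
    for (rv in r2) sums <- c(sums, sums + rv)
    v2 <- 2 * v
    pg <- sum(sums >= v2 - 1e-9) / length(sums)
    pl <- sum(sums <= v2 + 1e-9) / length(sums)
    p <- switch(alternative,
                greater = pg, less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
    method <- "Wilcoxon signed-rank test (exact enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (v - mu) / sigma
    p <- switch(alternative,
                greater   = stats::pnorm(z, lower.tail = FALSE),
                less      = stats::pnorm(z, lower.tail = TRUE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(p, 1)
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  test_result(c(V = v), p, alternative, method,
              data_name = paste0("x (n = ", n, "), mu0 = ", mu0))
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric tail probabilities conditioning on both margins. The
#' two-sided p-value sums the probabilities of all tables no more probable
#' than the observed one. The effect size is the sample (cross-product) odds
#' ratio `(a d) / (b c)`, reported as `Inf` when `b c = 0` with `a d > 0`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` tests enrichment of the `[1,1]` cell.
#' @return A [test_result] with the odds ratio as effect size.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2), alternative = "greater")
#' @export
fisher_exact_2x2 <- function(tab, alternative = "two.sided") {
  alternative <- .match_alternative(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b      # row 1 total
  nn <- c_ + d    # row 2 total
  k <- a + c_     # column 1 total
  supp <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(supp, m, nn, k)
  p <- switch(alternative,
              greater   = sum(probs[supp >= a]),
              less      = sum(probs[supp <= a]),
              two.sided = sum(probs[probs <= probs[supp == a] * (1 + 1e-7)]))
  num <- a * d; den <- b * c_
  or <- if (den > 0) num / den else if (num > 0) Inf else NaN
  test_result(c(a = a), p, alternative, "Fisher's exact test (2x2)",
              effect_size = c(`odds ratio` = or),
              data_name = "2x2 contingency table")
}

# enumerate all tables with the given margins, calling fun(table_vector)
# with rows flattened row-major; used by the exact r x c test.
.enum_fixed_margin_tables <- function(rowsums, colsums, fun) {
  r <- length(rowsums)
  fill_row <- function(row_idx, remaining_cols, acc) {
    if (row_idx == r) {
      # last row forced by the column margins
      fun(c(acc, remaining_cols))
      return(invisible(NULL))
    }
    target <- rowsums[row_idx]
    cvals <- remaining_cols
    cells <- integer(length(cvals))
    rec <- function(j, left) {
      if (j == length(cvals)) {
        if (left <= cvals[j]) {
          cells[j] <<- left
          fill_row(row_idx + 1L, cvals - cells, c(acc, cells))
        }
        return(invisible(NULL))
      }
      for (v in 0:min(left, cvals[j])) {
        cells[j] <<- v
        rec(j + 1L, left - v)
      }
    }
    rec(1L, target)
  }
  fill_row(1L, colsums, integer(0))
}

.table_logprob <- function(cells, rowsums, colsums) {
  sum(lgamma(rowsums + 1)) + sum(lgamma(colsums + 1)) -
    lgamma(sum(rowsums) + 1) - sum(lgamma(cells + 1))
}

#' Fisher's exact test for an r x c table
#'
#' Two-sided probability-ordering (Freeman-Halton) test conditioning on both
#' margins. Tables are enumerated exactly when the total count is at most 40
#' and the table fits within 3 x 5 (either orientation); otherwise the null
#' is sampled by Monte Carlo over tables with fixed margins (Patefield's
#' algorithm via [stats::r2dtable]) and the p-value uses the add-one
#' correction `(k + 1) / (n_mc + 1)` so it is always positive. Zero rows and
#' columns are dropped with a warning.
#'
#' @param tab r x c matrix of non-negative integer counts, r, c >= 2.
#' @param n_mc number of Monte-Carlo tables when enumeration is infeasible.
#' @param seed integer seed, required in Monte-Carlo mode.
#' @return A [test_result]; the statistic is the observed table's null
#'   log-probability.
#' @examples
#' fisher_exact_rxc(matrix(c(4, 0, 1, 2, 0, 3), nrow = 2))
#' @export
fisher_exact_rxc <- function(tab, n_mc = 10000, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(test_result(c(logprob = 0), 1, "two.sided",
                       "Fisher's exact test (degenerate table)",
                       data_name = "contingency table"))
  }
  rowsums <- rowSums(tab); colsums <- colSums(tab); total <- sum(tab)
  cells_obs <- as.vector(t(tab))
  lp_obs <- .table_logprob(cells_obs, rowsums, colsums)
  tol <- 1e-7

  exact_ok <- total <= 40 && min(dim(tab)) <= 3 && max(dim(tab)) <= 5
  if (exact_ok) {
    p_acc <- 0
    .enum_fixed_margin_tables(rowsums, colsums, function(cells) {
      lp <- .table_logprob(cells, rowsums, colsums)
      if (lp <= lp_obs + tol) p_acc <<- p_acc + exp(lp)
    })
    p <- min(p_acc, 1)
    method <- "Fisher's exact test (r x c, full enumeration)"
  } else {
    if (is.null(seed)) stop("seed is required for Monte-Carlo mode")
    sims <- .with_seed(seed, stats::r2dtable(n_mc, rowsums, colsums))
    lps <- vapply(sims, function(m)
      .table_logprob(as.vector(m), rowsums, colsums), numeric(1))
    k <- sum(lps <= lp_obs + tol)
    p <- (k + 1) / (n_mc + 1)
    method <- sprintf("Fisher's exact test (r x c, Monte Carlo, %d tables)",
                      n_mc)
  }
  test_result(c(logprob = lp_obs), p, "two.sided", method,
              data_name = "contingency table")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjustment,
#' implemented directly. BH-adjusted values never exceed the Bonferroni
#' adjustment element-wise.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), method = "bonferroni")
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(is.numeric(pvals))
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (method == "bonferroni") return(pmin(1, m * pvals))
  o <- order(pvals)
  ranked <- pvals[o] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' qPCR expression score
#'
#' Converts cycle-threshold (CT) readings to the common linear display scale
#' `40 - dCT`, with `dCT = ct_target - ct_reference`: higher scores mean
#' higher expression, and a target amplifying at the same cycle as the
#' reference scores 40.
#'
#' @param ct_target,ct_reference CT values in `(0, 40]` (vectorized).
#' @return `40 - (ct_target - ct_reference)`.
#' @examples
#' qpcr_expression_score(30, 20)
#' @export
qpcr_expression_score <- function(ct_target, ct_reference) {
  stopifnot(is.numeric(ct_target), is.numeric(ct_reference))
  ct <- c(ct_target, ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct > 40))
    stop("CT values must lie in (0, 40]")
  40 - (ct_target - ct_reference)
}
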