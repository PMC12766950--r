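# Small in-code fixtures shared across test files.

tiny_em <- function() {
  vals <- matrix(c(1, 2, 3, 4), nrow = 2,
                 dimnames = list(c("G1", "G2"), c("s1", "s2")))
  expression_matrix(vals, c(s1 = "lung", s2 = "lung"))
}

em_with_counts <- function(sizes) {
  # one gene, tissues with the given sample counts
  ids <- unlist(lapply(seq_along(sizes),
                       function(i) sprintf("t%d_s%02d", i,
                                           seq_len(sizes[i]))))
  tis <- rep(sprintf("tis%d", seq_along(sizes)), sizes)
  vals <- matrix(seq_along(ids), nrow = 1, dimnames = list("G", ids))
  expression_matrix(vals, setNames(tis, ids))
}

tiny_sc <- function() {
  cnt <- matrix(c(0, 1, 2,
                  3, 0, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("Wnt7b", "Bg1"), c("c1", "c2", "c3")))
  single_cell_counts(cnt,
                     c(c1 = "RZ", c2 = "RZ", c3 = "RZK"),
                     c(c1 = "Pit", c2 = "Pit", c3 = "Pit"))
}

# independent brute-force oracles ------------------------------------------

# all permutations of 1..n, recursively (oracle-side; small n only)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  out <- matrix(0L, nrow(p) * n, n)
  r <- 0L
  for (i in seq_len(nrow(p))) for (k in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(p[i, ], n, after = k - 1L)
  }
  out
}

# exact Spearman permutation p by direct enumeration over rank permutations
oracle_spearman_p <- function(x, y, alternative) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  pm <- perms(length(x))
  rhos <- apply(pm, 1L, function(ix) cor(rx, ry[ix]))
  tol <- 1e-9
  switch(alternative,
         greater = mean(rhos >= rho_obs - tol),
         less = mean(rhos <= rho_obs + tol),
         two.sided = mean(abs(rhos) >= abs(rho_obs) - tol))
}

# exact rank-sum p by enumerating group assignments with combn
oracle_rank_sum_p <- function(x, y, alternative) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, function(ix) sum(r[ix]))
  tol <- 1e-9
  pg <- mean(ws >= w_obs - tol); pl <- mean(ws <= w_obs + tol)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# exact signed-rank p by enumerating sign vectors with expand.grid
oracle_signed_rank_p <- function(x, mu0, alternative) {
  d <- x - mu0; d <- d[d != 0]
  ra <- rank(abs(d)); v_obs <- sum(ra[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  vs <- signs %*% ra
  tol <- 1e-9
  pg <- mean(vs >= v_obs - tol); pl <- mean(vs <= v_obs + tol)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Fisher 2x2 by direct enumeration of all tables with the observed margins
oracle_fisher_2x2 <- function(tab, alternative) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  supp <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, supp) * choose(r2, c1 - supp) / choose(r1 + r2, c1)
  switch(alternative,
         greater = sum(pr[supp >= a]),
         less = sum(pr[supp <= a]),
         two.sided = sum(pr[pr <= pr[supp == a] * (1 + 1e-7)]))
}

# Freeman-Halton r x c by brute force: enumerate the free (r-1) x (c-1)
# subtable on a grid and complete the last row/column from the margins
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n_tot <- sum(tab)
  r <- nrow(tab); cc <- ncol(tab)
  lp <- function(m) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(n_tot + 1) - sum(lgamma(m + 1))
  lp_obs <- lp(tab)
  free <- as.matrix(expand.grid(rep(list(0:max(c(rs, cs))),
                                    (r - 1) * (cc - 1))))
  p <- 0
  for (i in seq_len(nrow(free))) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- matrix(free[i, ], r - 1, cc - 1)
    m[seq_len(r - 1), cc] <- rs[seq_len(r - 1)] -
      rowSums(m[seq_len(r - 1), seq_len(cc - 1), drop = FALSE])
    m[r, ] <- cs - colSums(m[seq_len(r - 1), , drop = FALSE])
    if (any(m < 0)) next
    l <- lp(m)
    if (l <= lp_obs + 1e-7) p <- p + exp(l)
  }
  min(p, 1)
}

# naive O(N * |set|) ssGSEA running-sum oracle over every rank position
oracle_ssgsea_es <- function(profile, members, w = 1) {
  ord <- order(-profile, names(profile))
  ranked <- names(profile)[ord]
  wa <- abs(profile[ord])^w
  hit <- ranked %in% members
  nh <- sum(hit)
  inc <- ifelse(hit, wa / sum(wa[hit]), 0)
  dec <- ifelse(hit, 0, if (length(profile) > nh) 1 / (length(profile) - nh)
                else 0)
  rs <- cumsum(inc - dec)
  mx <- max(rs); mn <- min(rs, 0)
  if (mx >= -mn) mx else mn   # positive deviation preferred on exact ties
}
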