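---
title: "Methods: statistics behind a KRAS-driven WNT ligand screen"
author: "kraswnt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics behind a KRAS-driven WNT ligand screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kraswnt)
```

## The scientific question

Epithelial tumor cells normally depend on stromal niche cells for canonical
WNT ligands. When the MAPK pathway is activated by an oncogenic KRAS
mutation, gastric epithelial cells can start secreting their own ligand
(WNT7B), escaping that niche dependence. `kraswnt` implements the statistics
used to establish and generalize that axis: deriving a KRAS activity
signature from genotyped single-cell data, screening cancer cell-line panels
for a signature-to-ligand association tissue by tissue, scoring pathway
activity in pseudo-bulk profiles, and quantifying in-situ hybridization
(ISH) and expressing-cell-fraction evidence.

Everything is exercisable without external data: seeded generators emulate
each input with planted effects, so every claim the package makes about
recovery or calibration is checked against a known ground truth.

## The test kernel

All downstream modules route through a small set of tests implemented from
first principles (`rank_sum_test`, `signed_rank_test`, `spearman_test`,
`fisher_exact_2x2`, `fisher_exact_rxc`, `adjust_pvalues`). Implementing
rather than wrapping them is deliberate: the pipeline's conventions (exact
tail definitions, tie handling, odds-ratio flavor) are pinned down in code
and each function is verified in the test suite against an independent
brute-force oracle — full enumeration of group assignments, sign vectors,
rank permutations, or fixed-margin tables — plus base R's `wilcox.test`,
`fisher.test`, `cor.test` and `p.adjust` as cross-checks.

Conventions worth knowing:

* `rank_sum_test` defaults to the tie-uncorrected normal approximation on
  the rank sum with no continuity correction. This mirrors the plain
  large-sample z statistic used by common scientific-Python rank-sum
  routines, so p-values are comparable with pipelines built on them. The
  exact mode (dynamic program over doubled pooled ranks, usable to
  n1 + n2 = 30, ties included) exists for oracle testing and small designs.
* Exact two-sided p-values for the rank-based tests are twice the smaller
  tail, capped at 1.
* `fisher_exact_2x2` reports the sample (cross-product) odds ratio
  `(ad)/(bc)`, not the conditional MLE that `fisher.test` reports; `Inf` is
  returned when `bc = 0`. The choice is documented because the two flavors
  differ and the downstream effect sizes are these cross-product ratios.
* `fisher_exact_rxc` is the probability-ordering (Freeman–Halton) test. It
  enumerates all tables when the total count is at most 40 and the table
  fits in 3×5, and otherwise switches to Monte Carlo over fixed-margin
  tables (Patefield's algorithm via `r2dtable`) with the add-one correction
  `(k + 1)/(n_mc + 1)`, so reported p-values are never zero.
* `spearman_test` uses average ranks for ties; p-values come from the t
  approximation for n > 10 and from exact enumeration of all n!
  permutations below that (implemented in C++; the exact small-n null
  ignores tie multiplicity, a documented limitation). A constant input
  raises a classed error (`kraswnt_undefined_error`) instead of propagating
  NaN.
* `adjust_pvalues` offers Bonferroni and Benjamini–Hochberg. Differential
  expression defaults to Bonferroni because the single-cell toolchain whose
  thresholds the signature stage reproduces adjusts that way by default;
  BH is available everywhere.

## Synthetic data: what is emulated, and what is not

The generators define the study conditions; their defaults are fixed and
are not tuning knobs.

**Cell-line panel** (`simulate_cell_line_matrix`). A panel of 22 tissues
with 30 lines each by default — the breadth of a typical pan-cancer
cell-line collection in which every retained cancer type contributes more
than 20 lines. Planted association uses a Gaussian copula: in planted
tissues the latent normals of each signature gene and the target share
correlation rho, and values are pushed through the strictly monotone map
`log2(1 + exp(mu_g + sigma z))` onto a non-negative log2(TPM+1)-like scale.
Because Spearman correlation is invariant to monotone maps, the planted
rank correlation is exactly the copula-implied value
`(6/pi) asin(rho/2)` — the truth tables report that implied value (0.582
for rho = 0.6), and tests compare against it, not the nominal latent rho.

**Single-cell counts** (`simulate_single_cell`). Negative-binomial UMI
counts (default size 2) with lognormal gene means, cluster labels drawn per
genotype, a designated pathway gene set whose means are multiplied by
`exp(shift)` in the shifted genotype, and a target gene whose zero/non-zero
state is planted per (genotype, cluster) — expressing cells then draw a
zero-truncated negative binomial. Gene symbols are mouse-cased (`Pw001`,
`Wnt7b`) so ortholog mapping to upper-case human symbols is exercised for
real.

**ISH dots** (`simulate_ish`). Poisson dot counts per condition; cells with
dots draw a clustered-dot fraction above 0.10 with the configured
probability.

Not emulated: gene–gene co-expression structure, batch effects, doublets,
ambient RNA, library-size confounding between genotypes. Passing tests
therefore demonstrate that the *procedures* are correct and calibrated
under clean planted effects — not that any particular biological dataset
would reproduce.

## Signature derivation

`derive_signature` chains four steps: (1) a rank-sum differential
expression stand-in on CP10K/log1p values with fold change
`log2((mean_a + c)/(mean_b + c))`, pseudocount `c = 1e-9` on the CP10K
scale (a hurdle-model DE table produced externally can be injected through
`read_deg_table`, since the contribution here is the threshold-and-
intersect procedure, not the DE engine); (2) strict thresholds
adj_p < 0.01 and log2FC > 1 — a gene at exactly 0.01 is excluded, matching
the printed inequality; (3) ortholog mapping with dropped-gene reporting
and duplicate collapse; (4) intersection with a hallmark "KRAS signaling
up"-style set, ordered by the hallmark set, with provenance counts at every
stage. The fold change uses the mean-ratio estimate; whether a
coefficient-based estimate would shift membership near the boundary is
untestable without the original DE engine and is flagged as a limitation.

## The tissue screen

`tissue_screen` is the package's central fit. Per eligible tissue
(strictly more than 20 lines — a tissue with exactly 20 is out) and per
signature gene:

* Spearman rho against the target, two-sided p, and a display/cluster mask
  at unadjusted p > 0.05. No multiplicity correction is applied across the
  gene × tissue grid by default because the screen is descriptive at that
  stage; a BH mode exists (`adjust = "bh"`) but is off by default.
* A one-sided rank-sum comparison of target expression between the
  *highest* (Q1) and lowest (Q4) quartiles of the signature gene. Q1 being
  the highest quartile is fixed and tested — the reverse of the common
  ascending convention. Quartiles fill greedily (`ceiling` allocation:
  sizes 3,3,2,2 at n = 10) with ties broken by sample id so assignment is
  reproducible. The comparison runs on expression values; running it on
  fold changes relative to a tissue mean would give identical ranks up to a
  monotone shift and is not separately implemented.
* Genes are clustered on their binary significance profiles with the
  asymmetric binary (Jaccard) distance and average linkage — the exact
  routine pair (`dist(method = "binary")`, `hclust(method = "average")`)
  the screen's display convention comes from. Two all-zero profiles have
  undefined textbook distance (0/0); they are assigned distance 0 so the
  clustering stays total. This is a deliberate, documented deviation.
* A gene is *positive* in a tissue when rho > 0 and p < 0.05, and flagged
  when positive in at least 5 tissues (inclusive). Under a simulated global
  null this criterion flags well under 0.1% of genes (measured over 10,000
  null genes in the acceptance suite), i.e. it is conservative.

The displayed-subset question (showing only a dozen selected genes in a
figure) is presentational, not algorithmic: the fit computes all genes and
the CLI exposes a `--genes` subset flag rather than guessing a selection
rule. Tissues are not clustered, only genes.

### Power at the default recovery conditions

With rho = 0.6 (implied Spearman 0.582), 30 lines per tissue and 6 planted
tissues of 22, per-tissue detection power at two-sided alpha 0.05 is about
0.92, so the probability that one gene reaches 5 of its 6 planted tissues
is roughly 0.95, and "all 10 planted genes flagged" holds at most seeds but
not all — the recovery check in the acceptance suite runs at a seed fixed
in advance, and the acceptance script reports whatever count the supplied
seed produces. This marginality is a property of the stated conditions, not
of the implementation.

## Pseudo-bulk ssGSEA

`make_pseudobulks` draws 500 cells per replicate without replacement,
independently across 10 replicates per genotype (replicates may overlap —
bootstrap-style pseudo-replication with within-sample cells distinct), and
sums UMI counts; conservation against an independent column-sum oracle is
asserted in the tests. Profiles are CP10K/log1p-normalized and scored with
`ssgsea_score`:

* genes ranked by profile descending, ties broken lexicographically by gene
  id for determinism;
* hit increments `|x|^w / sum(|x_hits|^w)` with w = 1 (the classic weighted
  KS statistic; w is a knob because toolchains differ), miss decrements
  `1/(N - n_hits)`;
* ES is the running sum's maximum deviation from zero, sign preserved; on
  an exact magnitude tie the positive deviation is reported;
* signed sets (pathway footprints weighted both positively and negatively)
  score as ES(positive members) − ES(negative members); folding weights
  into the ranking instead is a recognized alternative, and the subset
  difference was chosen as the default because it keeps the unsigned path
  untouched and the two subsets interpretable;
* the null permutes gene labels: `times = 10000` random same-size hit sets,
  `perm_p = (k+1)/(times+1)` one-sided for enrichment, never zero. Sets
  overlapping fewer than `min_set_size = 5` profiled genes are reported
  absent rather than scored.

The implementation visits only hit positions (between hits the running sum
falls linearly, so extrema sit immediately after or before hits), making
10,000 permutations cheap; equality with the naive position-by-position
oracle is asserted exactly in the tests. Genotype comparison is the
one-sided rank-sum test on the 10-vs-10 replicate ES vectors. Within
`score_pathways` the permutation seed is derived per gene set, so all
samples share one permutation ensemble per set and identical profiles get
identical p-values.

## ISH scoring

The published class legend overlaps ("10–15 dots and/or >10% clustered" vs
">15 dots and/or >10% clustered"). `classify_ish_cell` resolves it with a
fixed precedence so that classification is total and single-valued:
Class 4 strictly requires more than 15 dots; the cluster escalator
(fraction > 0.10) promotes to Class 3 only, and only with at least 4 dots,
so an isolated 1–3-dot cell stays Class 1. The Class 2 cutoff for "no or
very few clusters" is implemented as fraction <= 0.10 and is an
interpretation, flagged as such. Class 0's "less than 1 dot per 10 cells"
is a field-level average: per cell it means 0 dots, and
`class_distribution(field_level = TRUE)` optionally reassigns Class 1 cells
to Class 0 in conditions whose mean is below 0.1 dots/cell.

Between-condition comparison builds the 2×5 class table and applies the
exact r×c test; zero classes are dropped with a warning. Pairwise 2×5
comparisons are the default interface; a pooled 3×5 table can be passed to
`fisher_exact_rxc` directly, since which variant a given figure used is
ambiguous. Expressing-cell fractions use the literal non-zero UMI rule with
no abundance threshold, tested with the exact 2×2 test.

## Numerical choices and degenerate inputs

* p-values are clamped into (0, 1]: permutation and Monte-Carlo p-values
  are add-one corrected, tail sums are floored at the smallest positive
  double.
* Exact-tail comparisons use absolute tolerances (1e-9 on rank statistics,
  1e-7 on table log-probabilities) so floating-point ties count as ties.
* Degenerate inputs fail loudly and early: constant vectors in correlation,
  all-zero deviations in the signed-rank test, negative or fractional
  counts, samples without tissue labels, cells without genotype labels.
  Zero rows/columns in contingency tables and empty sampled clusters are
  repaired with warnings instead, because they occur naturally in small
  synthetic draws.
* All generators take a mandatory integer seed and are deterministic given
  it; file writers emit plain text so byte-identity of artifacts across
  equal-seed runs is testable (and tested).

## Problem sizes

The test and acceptance runs use desk-scale sizes chosen to keep every
check sharp: 10,000 replicates for type-I calibration, 10,000 null genes
for the positivity-criterion false-flag rate, 22×30 panels for recovery,
2,000 cells per genotype with 10×500-cell pseudo-bulks and 10,000
permutations for the pathway separation, and 200-instance randomized sweeps
per oracle-equivalence check. These sizes make the whole suite run in
about a minute while leaving Monte-Carlo error well inside the asserted
bands.

## Known limitations

* The DE stand-in is a rank-sum test, not a hurdle model; boundary genes
  may differ from a hurdle-based run (injection path provided).
* The exact small-n Spearman null ignores tie multiplicity.
* The ssGSEA weighting exponent and signed-set combination each have one
  documented default among several in field use.
* The generators' independence assumptions (no co-expression, no batch
  structure) make recovery easier than on real data; calibration results
  transfer, recovery rates need not.
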