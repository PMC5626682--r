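---
title: "Models and methods behind intgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind intgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

intgen packages the statistical core of an integrative tumor-versus-normal
genomics workflow of the kind used to compare insulinomas with purified
normal beta cells: differential expression and exon usage, signed
co-expression modules, signature-to-module projection, a ranked mark axis,
allele-specific expression against a reference-bias null, and genomic
burden/recurrence summaries. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
method family leaves details open. Every empirical statement here is the
output of the package's own tests or scripts; nothing is quoted from
external data.

## Differential expression

Counts are transformed to log2 counts-per-million,
`log2((y + c) / ((L + 2c)/1e6))` with pseudocount `c = 0.5` and library
size `L` the raw column sum. The effective library size is deliberately
the raw total: a robust scaling factor (TMM-style) is out of scope, and
keeping the choice isolated inside `log_cpm()` makes it swappable. The
consequence — compositional shifts when a large fraction of the
transcriptome moves — is real and is discussed under Limitations.

Each gene's log-CPM is regressed on group (tumor vs control) plus any
metadata covariates (sex, platform). The per-gene residual variance is
shrunk toward the grand mean variance with a prior of `prior_df = 4`
degrees of freedom, giving a moderated t with `n - p + 4` df. This is a
deliberate, simpler stand-in for precision-weighted pipelines
(voom/limma): the weighting machinery is established prior art, while the
contribution here is the surrounding workflow; the moderation keeps small
cohorts from being dominated by unstable per-gene variances. Direction
calls follow the study convention: significant at FDR ≤ `fdr_de` (default
0.01) with logFC ≥ 0 is "up" (ties at exactly 0 go up), negative logFC is
"down", all else "ns".

## Exon usage and the Simes combination

Isoform exon models are flattened into disjoint counting bins
(`flatten_exons()`, split at every exon boundary via interval disjoint).
The exon-level fit reuses the moderated linear model; a bin's usage logFC
is its logFC minus the mean logFC of the gene's other bins, tested with a
moderated t. Gene-level evidence combines two ways: a weighted F-test for
heterogeneity of bin logFCs, and the Simes combination
`min_k (m * p_(k) / k)` over the ordered per-bin p-values, BH-adjusted
across genes. `m` counts only tested bins; genes with a single bin are
skipped (their relative usage is identically zero by the formula
`rel_i = log2(2^x_i / sum_j 2^x_j)`, which always satisfies
`sum_j 2^rel_j = 1`).

## Signed co-expression modules

The network is signed: adjacency `a_ij = ((1 + cor_ij)/2)^beta` with
`beta = 12` (the usual signed-network convention), so anti-correlated
genes are maximally separated rather than joined. Genes are clustered on
topological-overlap dissimilarity with average linkage and a **single
static cut** at `merge_height = 0.99`; clusters below `min_module_size =
30` genes fall to the unassigned label 0. The static cut is a deliberate
simplification of dynamic tree cutting: it is deterministic, has one
interpretable parameter, and is easy to test. Module eigengenes are the
first right singular vector of the standardized module block, oriented so
their correlation with the module's mean profile is positive; kME is the
Spearman correlation of every network gene with every eigengene, with
membership p-values (MMP) from the t approximation on `n - 2` df (exact
Spearman for n ≤ 10) and membership called at MMP < 0.01 — computed
against *all* network genes, not just module members. Hub genes rank by
intramodular connectivity (row sums of the module's adjacency block,
diagonal excluded; ties break lexicographically).

Because no automatic soft-power selection is performed, `beta`,
`merge_height` and `min_module_size` are explicit configuration with the
defaults above.

## Signature projection and the FDR score

Projection is an exact hypergeometric test per signature x target pair
within a stated gene universe: one-sided `P[X >= k]` for
over-representation questions (up-DEGs vs a mark; mutated genes vs an
annotation panel), two-sided by the minlike convention (sum of all table
probabilities at most the observed, relative tolerance 1e-7) for the
module heat-map, matching common exact-test implementations. The odds
ratio is the plain cross-product with a Haldane 0.5 correction only when
a zero cell would make it undefined (never affecting p). Fold enrichment
is `k*N/(n_sig*n_tgt)` — the observed/expected definition, chosen over an
odds-ratio reading and flagged as such. Calls use strict inequalities:
over if fold > 2 and FDR < 0.01, under if fold < 0.6 and FDR < 0.01. The
FDR family is all pairs of one projection run, jointly.

The FDR score compresses the matrix for visualization: 0 wherever
FDR > 0.05; otherwise `-log2(FDR)` signed positive for odds ratio > 1 and
negative for < 1, capped at |50|; FDR = 0 maps to the cap; a significant
record at odds ratio exactly 1 has no direction and scores 0.

## The DE-ranked mark axis

Genes are ordered along one axis and each signature becomes a 0/1 track
smoothed by a sliding window of `2*flank + 1 = 201` genes (truncated at
the ends, so the curve stays in [0, 1]; interior windows are exactly 201
genes). Two orderings are provided because the natural-language
description of this ranking is self-contradictory (up-genes "ascending"
followed by down-genes "descending" cannot also put the most significant
genes of both signs at the ends): the default `signed_significance` sorts
by `sign(logFC) * (-log10 FDR)` ascending, placing significant
down-genes at one end and significant up-genes at the other;
`literal_blocks` keeps the literal two-block reading. Neither is asserted
as the historical intent; both are tested.

## Allele-specific expression

Sites need ≥ `min_ase_depth = 30` supporting reads, must not fall in the
repeat/low-mappability mask (BED, 0-based half-open; positions convert
only inside the reader), and must not be an A/G pair or its
reverse-complement T/C (the RNA-editing signature). The empirical null
reference fraction `p0` is the **median** of per-site pooled reference
fractions among passing sites, per group — the median resists
contamination by genuinely imbalanced loci, and group-specific estimation
costs little while allowing the two tissues different bias. Under
reference bias this recovers ≈ 0.54.

The quasi-binomial test pools a locus's S samples within a group:
`p_hat = sum(y)/sum(n)`, Pearson dispersion
`phi_hat = max(1, sum((y - n*p_hat)^2/(n*p_hat*(1-p_hat)))/(S-1))`
(1 when S = 1), Wald `z = (p_hat - p0)/sqrt(phi_hat*p_hat*(1-p_hat)/sum(n))`
with a two-sided normal p, BH FDR across loci within the group. This is
equivalent to an intercept-only quasi-binomial fit tested against an
offset null; the test family fixes no single estimator, so
the pooled-Wald operationalization is a documented choice, as are:
testing pooled-per-group rather than per sample, and requiring a locus to
appear in at least one sample of *each* group before testing. Degenerate
pooled fractions use the continuity correction `(sum(y)+0.5)/(sum(n)+1)`.

## Genomic summaries

Burden counts protein-altering somatic variants per sample, including
zero-variant samples in the denominator, and reports the mean to one
decimal. Recurrence requires ≥ 2 *distinct* mutated samples per gene.
Panel coverage marks a sample as hitting a panel gene through a variant
or any gain/loss/cnLOH segment overlapping the gene by ≥ 1 bp, and
reports the covered fraction as an integer percent with round-half-up
(22/26 → 85%). CNV recurrence tracks tile each chromosome into 1-Mb bins;
a sample counts once per bin per class on any ≥ 1 bp overlap — the
rendered figure this emulates is coarse (one line per 20% of samples), so
the overlap rule is made explicit rather than inferred.

## The synthetic-data generator

The generator is the package's study stand-in, with defaults fixed once
as the experimental conditions: 2000 genes, 20 samples per group, four
50-gene modules, 15% DE genes at |logFC| = 2 (random sign), NB dispersion
`alpha = 0.1` (`Var = mu + alpha*mu^2`), module latent factors N(0, 0.8)
on the log2 scale with loading 1 (within-module correlation ≈ 0.7),
log-normal library factors (sd 0.3) to exercise CPM normalization. Exon
bundles draw gene totals identically in both groups and shift one bin's
share (0.25 → 0.50 by default) in tumors only, so totals are matched
while usage differs. Allele counts realize the reference bias
*mechanistically*: loci are simulated at true fraction 0.5 and each
alternate read is dropped with probability `2 - 1/0.54 ≈ 0.148`, so the
null-fraction estimator is validated against a process, not its own
parameter; planted imbalanced loci (100 of 5000, true fraction 0.8) use
their fractions directly. Mark signatures include up-DEGs with
probability 0.9 and background genes with probability 0.1; proliferation
signatures sample module-1 genes at 0.8. Variant tables plant a small set
of recurrent genes (2-3 tumors each) plus background singletons over
*distinct* genes (so planted recurrence is the only recurrence);
segments plant a chr7 gain (~40% of tumors) and chr11 loss (~20%).

What the generator does **not** emulate: GC/length biases, correlated
gene-gene noise beyond the module factors, isoform-level structure,
mappability-driven ASE artifacts beyond a uniform dropout, subclonal CNV
fractions. Passing recovery tests therefore demonstrates the statistics
are implemented correctly and calibrated under their stated model — not
that they are robust to every artifact of real sequencing data.

## Numerical and testing choices

- Fixed seeds expand into per-stage substreams by a stable string hash of
  the stage name, so one stage's stream does not depend on which stages
  ran before it; reruns are byte-identical.
- Exact-test p-values are discrete, hence conservative; null-calibration
  tests assert rejection-rate bounds rather than a continuous KS
  uniformity statistic (which fails mechanically on ties). KS is used
  where p-values are continuous (moderated t under the null).
- Module-recovery tests run on bundles with modules but no DE genes: a
  planted group effect itself induces co-expression among DE genes —
  realistic, but "truth" labels those genes background, which an
  agreement index would penalize even when detection is correct.
- The overdispersed quasi-binomial calibration uses 20 samples per group
  per locus (cohort scale); with few samples the
  Pearson dispersion estimate is noisy enough that the Wald test runs
  slightly hot. The null calibration uses 5 samples, matching the planted
  ASE recovery condition.
- Problem sizes in the test suite (e.g. 300-2000 genes, 500-5000 loci,
  20-50 replicate runs) are chosen to make Monte-Carlo bounds sharp at
  desk scale; generator defaults themselves never change per test.

## Limitations

- Raw-column-sum library sizes leave a compositional residual: in small
  transcriptomes where planted modules are a large share of counts
  (e.g. 100 module genes of 400), the module factors move column totals
  and induce background-background correlation ~0.2, which a clustering
  step will honestly detect. At the default 2000-gene scale the residual
  correlation is ~0.03 and negligible.
- The moderated linear model has no precision weights, so at the default
  conditions the realized false-discovery proportion at FDR 0.01 runs a
  few percent when 15% of genes are DE — adequate for the planted-truth
  studies here, not a replacement for a weighted pipeline on real counts.
- The static tree cut will not separate nested or close modules the way
  dynamic cutting can; `merge_height` trades sensitivity against noise
  clusters.
- The ASE test is asymptotic (Wald); at minimal depth (30 reads, one
  sample) its discreteness is visible, which is why calls rest on BH FDR
  across many loci rather than single-locus p-values.
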