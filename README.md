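# pathtune

Do the inherited risk loci of a disease co-incide with the cis-acting
elements of a specific transcriptional pathway? `pathtune` implements the
complete statistical pipeline for answering that question, motivated by
the renal-cancer case in which the HIF pathway — constitutively activated
by VHL loss — shows marked excess overlap between its ChIP-seq-defined
binding sites and GWAS susceptibility polymorphisms, supporting a
"pathway tuning" model of cancer development.

The package is aimed at statistical geneticists and regulatory genomicists
who want the individual ingredients (LD clumping, interval permutation
tests, pre-ranked GSEA, negative-binomial eQTL tests) as tested, reusable
functions, plus a synthetic-data module that generates every input with
planted ground truth so the whole analysis can be exercised and validated
without any external data.

## What it computes

**Risk loci.** From SNP-level summary statistics and a genotype reference
panel, independent index SNPs are selected iteratively (most significant
first, excluding everything within 500 kb or at r² ≥ 0.2), and each locus
becomes a haplotype block: the index SNP plus all SNPs with r² ≥ 0.8,
where r² is the squared correlation of dosage vectors. Two tiers:
supra-threshold (p ≤ 5×10⁻⁸) and sub-threshold (10⁻⁴ > p > 5×10⁻⁸,
defined after excluding everything proximate to a supra-threshold index).

**Consensus binding sites.** Peaks from replicate ChIP-seq datasets are
clustered by ≥ 1 bp single-linkage overlap; clusters present in ≥ 2
datasets are kept as union spans.

**Permutation enrichment.** The observed overlap count is compared with
an expected frequency distribution built by shuffling, in either
direction: haplotype blocks relocated uniformly around the genome, or
peaks relocated within an enhancer background. The empirical p-value is
m/n_iter, the fraction of iterations whose null count reaches the
observed one (reported as a bound `p < 1/n_iter` when m = 0):

```
p = #{ iterations : null count >= observed } / n_iter
```

**Gene-level follow-up.** Genes are assigned to loci by proximity
(± 25 kb) or promoter interaction (TSS ± 2 kb at a chromatin-interaction
target), ranked by the combined metric

```
pi_i = phi_i * (-log10 pv_i)
```

(log2 fold-change times significance of differential expression, both
from the package's own negative-binomial GLM), and the assigned set is
tested by weighted pre-ranked GSEA with a gene-label permutation null.
Genotype-stratified expression is tested by fitting counts to a
negative-binomial GLM against genotype and referring the likelihood
ratio against the genotype-free model to a chi-square distribution.

## A worked example

```r
library(pathtune)

cfg <- run_config(plan = simulation_plan(seed = 1), n_iter = 20000,
                  n_perm = 5000, seed = 1)
report <- run_full(cfg)
summarize_report(report)
```

```
Risk loci: 12 supra-threshold, 6 sub-threshold; 52 consensus peaks
  supra_direct    observed 6, expected 0.25, p < 5e-05
  supra_proximal  observed 6, expected 1.91, p = 0.00635
  supra_converse  observed 6, expected 1.39, p = 0.0018
  sub_direct      observed 3, expected 0.12, p = 1e-04
  GSEA: 35 assigned genes, ES = 0.68, NES = 0.90, p = 0.718
  eQTL at rs0000003: 4/60 genes with chi-square p < 0.05
```

The plan plants 12 genome-wide-significant loci, 6 of them inside
binding-site peaks that cover under 1% of a 20 Mb toy genome. Clumping
recovers all 12; the direct overlap of 6 loci against a null expectation
of 0.25 is an enrichment that no shuffle out of 20,000 matched
(p < 5×10⁻⁵); the converse test (peaks shuffled within enhancers) and
the ± 25 kb proximity test agree; and 3 planted sub-threshold loci
replicate the pattern in the independent second tier. The genotype test
at the first locus recovers the planted per-allele fold-changes. The
printed fixture of the thirteen published renal-cancer loci is available
via `table1_fixture()`, and `table1_summary()` recomputes its headline
counts (13 loci; 4 overlapping a binding site; 7 within 25 kb; 8 linked
by proximity or long-range interaction) with the package's counting
operations.

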