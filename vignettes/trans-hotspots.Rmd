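---
title: "Mapping trans-regulatory hotspots from gene-panel expression GWAS"
author: "teqhot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-regulatory hotspots from gene-panel expression GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teqhot)
```

# The model

`teqhot` analyses the expression of a gene panel (tens of genes belonging to
one pathway) across a panel of inbred lines, asking where in the genome
natural variation coordinately regulates the pathway. The statistical unit is
the single-marker association: for every SNP $j$ and gene $g$,

$$ y_g = \alpha + \beta_j x_j (+ C\gamma) + \varepsilon $$

where $y_g$ is the (already normalized) expression of gene $g$, $x_j \in
\{0,1,2\}$ counts the alternate allele, $C$ is an optional covariate matrix
and $\varepsilon$ is Gaussian. $\beta_j$ is estimated by ordinary least
squares and tested with a two-sided $t$ test. This deliberately simple model
assumes complete genotypes, expression that is roughly Gaussian after
upstream normalization (e.g. a Box–Cox transform of counts), and no
population-structure correction — kinship and mixed models are out of scope;
covariates (for instance expression principal components) are the opt-in
escape hatch.

Associations at $P \le 10^{-4}$ are retained. This permissive per-test
cutoff is not where significance is claimed; significance comes from
*co-occurrence*: a locus matters when it is associated with many panel genes
at once.

## Hotspot tiers

Three increasingly window-based definitions are implemented, each counting
**distinct genes per tissue**:

* a **hot SNP** is a trans-acting SNP with associations to at least
  `minGenes` (default 8) panel genes;
* a **top SNP** is, per gene and exclusive 250 kb window, the single
  lowest-$P$ trans SNP; a **hot top SNP** is a position that is top SNP for
  at least 8 genes — this collapses towers of correlated associations to one
  representative per locus;
* a **windowed hotspot** is an exclusive 40 kb tile containing top SNPs for
  at least 8 genes.

Cis and trans are defined by distance from the SNP to the nearest gene-body
edge (0 if inside; 1-based coordinates): cis within 50 kb, trans at 1 Mb or
more or on another chromosome. SNPs between 50 kb and 1 Mb on the same
chromosome fall in an explicit `proximal-excluded` class, because only the
two extremes have a clean interpretation; treating the gap as either class
would contaminate both. The thresholds are arguments
(`cisKb`, `transMb`), so "local trans" analyses can redefine the bands.

## Null models

Under independence, with $t$ top SNPs over $G$ genes and $W$ windows, a
window carries a top SNP of a given gene with probability $p = (t/G)/W$, and
the probability that a window is a hotspot is the upper tail
$P(X \ge m)$, $X \sim \mathrm{Binomial}(G, p)$; the expected number of
hotspot windows is $W \cdot P(X \ge m)$. The tail is accumulated in log
space (`lchoose` + log-sum-exp), because at the default parameters tail
probabilities reach $10^{-23}$ and naive summation underflows.

The permutation null drops each tallied association independently and
uniformly into one of $W$ bins and counts bins passing the hotspot rule,
averaged over 1000 permutations; the FDR is that mean over the observed
hotspot count. Two counting rules are provided because the procedure is
ambiguous in prose: `countMode = "associations"` (a bin with $\ge m$
assigned associations; the literal reading, and the default) and
`countMode = "genes"` (a bin receiving associations from $\ge m$ distinct
genes; stricter, and the rule the real hotspot definition uses). The two
coincide when per-gene tallies are small relative to the bin count; tests
assert the genes mode never exceeds the associations mode.

Two pragmatic conventions follow reported-arithmetic practice: probabilities
are *reported* at 3 significant figures and FDRs at 2 (stored values keep
full precision), and `binomialHotspotExpectation()` accepts an explicit
`perWindowProb` so that a tail computed from a rounded rate — the way such
chains are usually printed — can be reproduced exactly.

Both nulls assume genes are expressed independently within a sample. That is
false for a co-regulated pathway — shared environment, sampling time and
developmental stage all induce positive covariance — so hotspot counts
under these nulls are anti-conservative to an unknown degree. The package
surfaces the assumption rather than hiding it; molecular follow-up, not a
smaller FDR, is the fix.

## Expression indices

The Z-score of gene $g$ in sample $i$ is $(e_{gi} - \bar e_g)/s_g$ with the
sample standard deviation ($n-1$). The index of a gene set is the unweighted
per-sample mean of those Z rows. Which SD convention the upstream studies
used is typically unstated; $n-1$ matches statistical-software defaults, and
the choice only rescales every index by one constant, so GWAS rank order and
threshold crossings at a given quantile are unaffected. Zero-variance genes
become all-zero rows (with a warning) instead of being dropped, keeping set
sizes stable. Because the index is linear in the per-gene Z-scores, it is
invariant to per-gene affine rescaling of the input — an assertion in the
test suite.

Paired mutant/wild-type phenotypes get derived traits per timepoint:
`Ratio = MT/WT` and `Diff = WT − MT` (so a suppressed mutant gives a small
positive difference); a zero WT reading yields an NA ratio, logged.

## Candidate annotation

Hot SNPs: genes with a transcription start site within 125 kb (inclusive)
are split by genomic side of the SNP — upstream/downstream refer to the +
orientation of the genome, not gene strand, since ranking is by TSS distance
irrespective of strand — and the nearest 3 per side are ranked 1..3. Ties in
TSS distance break to the smaller gene start, then the lexicographically
smaller id, so output is deterministic and invariant to annotation row
order. A gene whose body overlaps the SNP is one `inside` record at distance
0. Windowed hotspots use the min/max of member-SNP positions as the
boundary: overlapping genes are `inside`, plus at most one flanking gene per
side within 125 kb of the edge.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the study
conditions the tests run under: 300 lines, a 10-chromosome × 20 Mb toy
genome (a desk-scale stand-in for a multi-Gb genome that keeps window
arithmetic fast), biallelic SNPs with per-SNP alternate-allele frequencies
drawn uniformly from `mafRange` (default 0.05–0.5; frequencies can fall
below the filter so `recodeAndFilter()` has work to do), dosages drawn as
two independent allele draws, per-gene cis effects $\sim N(0, 0.5)$ at each
gene's nearest SNP, planted trans regulators with effect 0.5 expression
units per allele on ≥ 8 target genes, and homoscedastic Gaussian noise with
SD 0.5. One regulator target can be designated sign-flipped in one tissue,
emulating a pathway gene divergently regulated in a single condition.
Phenotypes are paired mutant/wild-type readings whose focal-SNP effect
exists only in mutants (epistasis: the mutant background is required for the
variant to matter).

Design choices worth recording:

* **Planted regulators are common variants placed in trans.** The test
  fixtures put the regulator on a chromosome carrying none of its target
  genes and at a SNP with MAF near 0.3. A trans hotspot tagged by an allele
  at the 0.05 filter boundary is barely mappable at $n = 300$
  ($\mathrm{var}(x) \approx 0.1$ vs $\approx 0.42$ at MAF 0.3), and a
  "trans" regulator within 1 Mb of a target would be silently excluded by
  the classification — both are fixture artifacts, not properties under
  study, so the generator's planted architecture avoids them by
  construction.
* **Determinism.** A single integer seed drives everything; per-stage
  substreams are derived from it (genotypes at `seed`, cis effects at
  `seed + 1`, per-tissue noise at `seed + 1000 +` a tissue-label hash,
  phenotypes at `seed + 2000`), so adding a tissue never perturbs another
  stage's draws and identical configurations are bit-identical.
* **No effect-size distribution is claimed.** Planted effects are
  calibration choices, not estimates of natural trans-variant effects.

What the generator does **not** emulate: linkage disequilibrium, population
stratification, relatedness, realistic allele-frequency spectra,
heteroscedastic or count-based expression noise, and inter-gene expression
correlation beyond the planted architecture. Passing tests therefore
demonstrate that the machinery is correct and calibrated under its stated
model — not that real-data hotspot counts are unbiased, which the
independence caveat above already rules out.

# Numerical conventions and degenerate inputs

* Perfect fits (residual $r^2$ within $10^{-12}$ of 1) report $P = 0$
  rather than an underflow-dependent denormal; downstream logic only
  thresholds.
* A constant trait gives $\beta = 0$, $P = 1$; a zero-variance SNP reaching
  the scan is an error (the filter should have removed it).
* Top-SNP ties break by smaller $P$, then smaller position, then
  lexicographic SNP id — fully deterministic.
* Windows are half-open $[iW, (i+1)W)$ anchored at coordinate 0; a genome
  of length $L$ contributes $\lfloor L/W \rfloor$ windows plus one for any
  remainder (2.5 Gb in 40 kb tiles gives 62,500).
* In the divergence tabulation, a SNP whose non-focal genes split evenly
  between signs has no majority; it is reported with `divergent = NA` and
  excluded from the divergence-fraction denominator.
* Effect normalization by trait mean is an export-layer option only;
  stored coefficients are never rescaled.

# Problem sizes used by the test suite

Unit tests run on matrices of tens of lines and SNPs. The calibration and
recovery suites use the generator's study conditions: a null scan of 300
lines × 5,000 SNPs × 20 genes for the $10^{-4}$ tail calibration; 100
seeded replicates of the planted-regulator study (300 lines × 500 SNPs × 70
genes) for three-tier recovery and for index-GWAS detection, asserting
success in at least 95 of 100 replicates; and the permutation null at its
full published scale (48,734 associations over 62,500 bins × 1,000
permutations), checked against the analytic multinomial-bin expectation
within three Monte-Carlo standard errors. These sizes are the package's
definition of a desk-scale study: large enough for the asymptotics the
checks rely on, small enough to be re-run routinely.

# Limitations

* No kinship/mixed-model correction, imputation, LD-aware clumping,
  conditional analysis or fine-mapping.
* Missing genotypes are unsupported; inputs are assumed imputed/complete.
* Differential-expression calling and GO enrichment are consumed as gene
  lists, not performed.
* The hotspot nulls assume independent gene expression (see above) and the
  permutation assigns associations independently (multinomial), not by
  permuting genomic positions, so LD structure is not preserved under the
  null.
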