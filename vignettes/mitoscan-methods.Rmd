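---
title: "Methods: case-control scanning of whole mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control scanning of whole mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

## The problem

mitoscan analyses cohorts of aligned whole-mitogenome consensus sequences
split into two phenotype groups (labelled `F` and `NF` throughout, after the
finished/not-finished design it was built for). The mitochondrial genome is
haploid, maternally inherited and recombination-free, so association
analysis reduces to comparing per-position allele frequencies between
groups, while lineage structure (haplogroups) must be checked as a
confounder. The package covers the whole chain: ingest and filtering,
per-site counting, the allele-frequency-difference (δ) scan with 3-SD
outlier flagging, contingency statistics with odds ratios, haplogroup
classification with Wright's F~ST~ and AMOVA-style Φ~ST~, codon-level
annotation of flagged variants, and a seeded synthetic-cohort generator
used to validate every stage.

## Input filtering

Two rules are applied before counting, both exposed in `cohort_config()`:

* **Heteroplasmy** (two bases at one position within one individual) is
  accepted when the minor:major ratio is at least `heteroplasmy_min_ratio`
  (default 0.25, i.e. 1:4). In consensus FASTA input heteroplasmies arrive
  as two-base IUPAC codes; how they enter the counts is governed by
  `heteroplasmy_policy`. The default, `exclude_site_sample`, drops that
  sample at that site, because a consensus code carries no information
  about which allele dominates. `count_major` resolves the code to the
  pooled-majority base and `iupac` credits half a count to each base; both
  alternatives exist because published analyses rarely state their choice
  and the difference matters only at sites with many heteroplasmic
  carriers.
* **Homopolymer indels**: insertions and deletions anchored inside a
  single-base reference run of at least `homopolymer_min_run` bases
  (default 5) are masked and treated as the reference. Indel calls inside
  poly-C/poly-T tracts are dominated by within-individual replication
  slippage rather than inherited variation. The threshold of 5 is our
  choice; published descriptions of the rule name the regions but not a
  run length, and 5 is the shortest run at which MiSeq-class indel error
  becomes appreciable.

Positions where a sample carries `N` (or a three/four-base ambiguity code)
contribute no count for that sample. The per-site, per-group table
therefore conserves: counted + excluded = group size.

## The δ scan

Each site is polarized to the cohort-wide major allele (pooled argmax,
alphabetical tie-break for determinism). For two groups with non-major
allele frequencies $p_F$ and $p_{NF}$, the biallelic statistic is

$$\delta = |p_F - p_{NF}|.$$

At multiallelic sites the default generalization is the total-variation
distance $\tfrac12\sum_a |p_{F,a} - p_{NF,a}|$, which reduces exactly to
$|p_F - p_{NF}|$ when only two alleles segregate; the maximum non-major
per-allele difference is available as an alternative.

Outliers are flagged by comparing δ to a threshold built from the sample
(n−1) standard deviation of δ over polymorphic sites only (monomorphic
sites have δ = 0 by construction and would dilute the spread estimate).
Two readings of "greater than three standard deviations" are implemented:

* `three_sd_about_zero` (default): flag δ > 3·sd(δ). This is the most
  literal reading of the phrase.
* `mean_plus_three_sd`: flag δ > mean(δ) + 3·sd(δ).

The two rules behave differently under a dense null: δ over null sites is
approximately half-normal, so the literal threshold 3·sd(δ) ≈ 1.8σ of the
underlying normal admits a few percent of null sites, whereas the
mean-anchored rule is conservative (well under 1%). Both behaviours are
asserted in the test suite; the default follows the literal phrasing and
the alternative is one flag away. If sd(δ) is exactly zero (degenerate
cohorts) nothing is flagged and a warning is raised.

## Association statistics

For a flagged site the 2×2 table is group × (non-major, major) allele
mass. `two_by_two_test()` applies Pearson's chi-square with 1 df and no
continuity correction when all expected cells are ≥ 5, otherwise Fisher's
exact two-sided test, recording the branch taken. No Yates correction is
used: on the reconstructed 29/59 worked-example table the uncorrected
chi-square reproduces the reference p-value (~0.011) while the corrected
one does not.

The odds ratio is the cross-product $(ad)/(bc)$. The default interval is
the Woolf log interval $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$
with the Haldane–Anscombe +0.5 correction when any cell is zero; the exact
conditional (Fisher) interval is available via `method = "exact"` and the
method used is always recorded. The exact interval is wider than Woolf on
moderate tables, which matters when comparing against published intervals
whose method is unstated.

No multiple-testing correction is applied by default (scan-then-test
designs often report nominal p-values); Bonferroni over the
polymorphic-site count and Benjamini–Hochberg are available in
`site_association()`.

`t_from_summary()` and `cohens_d_summary()` operate on printed summary
statistics (mean, SD, n). Cohen's d defaults to the root-mean-square
denominator $\sqrt{(s_1^2+s_2^2)/2}$: on the worked-example age summaries
(27.7 ± 4.2 vs 28.6 ± 4.0) this form, and only this form, reproduces the
reference effect size 0.219447 to six decimals; the df-weighted pooled
denominator is provided for convention compatibility. Note that a t
statistic recomputed from rounded printed summaries will generally not
match a published value computed from raw data; the package treats such
recomputed values as approximations, not oracles.

## Group differentiation

`haplogroup_fst()` treats haplogroups as alleles of a single locus and
computes the heterozygosity-partition index
$F_{ST} = (H_T - H_S)/H_T$ with $H_T = 1 - \sum_k \bar p_k^2$ and
$H_S = \sum_g (n_g/N)(1 - \sum_k p_{gk}^2)$ — the most direct reading of
"Wright's F-statistics" on categorical haplotypes. No sample-size
correction is applied by default; the estimate is reported raw (it may be
slightly negative for balanced spectra).

`phi_st()` is a two-level analysis of molecular variance on squared
pairwise mismatch distances: $SSD_{total} = \frac{1}{2N}\sum_{ij}d_{ij}^2$,
within-group SSD analogously per group, mean squares with df $G-1$ and
$N-G$, the among-group component scaled by
$n_0 = (N - \sum_g n_g^2/N)/(G-1)$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Distances count
positions where both sequences carry an unambiguous base and differ;
ambiguous positions are dropped per pair (pairwise deletion), with per-pair
usable-site counts kept as an attribute.

Both estimators take their significance from label permutations with
$p = (b+1)/(m+1)$ where $b$ counts permuted estimates ≥ the observed one;
the default is 10,000 permutations and the seed is recorded in the result,
making p-values bit-reproducible. The frequency-based and distance-based
estimators agree qualitatively but not numerically on the same data (they
decompose different quantities); the package reports both and never
converts one into the other.

`nj_tree_newick()` provides a neighbor-joining tree over the mismatch
distances as a quality-control view (samples should cluster by
haplogroup); it is deliberately not a substitute for model-based
phylogenetics.

## Haplogroup classification

The classifier scores each sample's variant set (tokens like `11914A`)
against every node of a user-supplied definition tree in which defining
variants accumulate from root to node: score = matched/expected along the
root→node path, the root scoring 1 with 0 expected by convention. The best
node maximizes the score, with ties broken by greater depth (more specific
call) and then alphabetically — all deterministic. Scoring is an
unweighted match fraction; phylogenetic weighting of individual variants
is out of scope, and back-mutations count as plain mismatches. The
definition table is an input file rather than bundled phylogeny data,
because haplogroup trees are versioned external knowledge; the synthetic
generator emits a matching table for its simulated tree.

Macro-lineage simplification is a longest-prefix lookup (`L3e2b` → `L3`,
`H1a` → `H`) against an ordered prefix table; unmatched names map to
`OTHER` with a warning.

## Consequence annotation

The gene model (start, end, strand, frame offset, coding flag, optional
wrap flag for the gene spanning the circular origin) is an input file.
Codon location is pure reading-frame arithmetic, mirrored for minus-strand
genes and unrolled past the origin for wrapped genes; the shipped
ND4-like fixture places position 11914 in codon 385, third position. Ref
and alt codons are read from the reference with the substitution applied
and translated under a supplied code table (a vertebrate mitochondrial
table ships with the package; all 64 codons must resolve, unknown codons
are an error, never silent). The shipped ND4-like span is trimmed by one
base relative to the genomic gene so that it is a whole number of codons
(the genomic transcript ends in an incomplete stop completed by
polyadenylation, which a codon-arithmetic model cannot represent).

For synonymous changes the codon-usage (molar) ratio
usage(alt)/usage(ref) on the frequency-per-thousand scale quantifies how
strongly usage bias favours one codon: the shipped human-mitochondrial
fixture records ACA = 32.7 and ACG = 2.6 per thousand, giving the
ACA/ACG ratio 12.6 at one decimal.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not mitochondrial biology in full: a uniform-random reference
with an embedded poly-C tract, founders built by accumulating defining
variants along a simulated haplogroup tree, and per-sample draws of
haplogroup (group-specific probabilities), planted-site alleles
(per-group Bernoulli), Poisson private mutations, IUPAC heteroplasmies
and single-base deletions in the tract. All draws come from one seeded
stream in a fixed order, so a config is a complete recipe: the same seed
gives byte-identical FASTA/VCF/TSV/JSON output, and the truth file records
assignments, realized planted counts, heteroplasmies and indels.

Defaults mirror the study design the package targets: 16,569-bp genome,
groups of 29 and 59, twenty-two haplogroups with a shared spectrum in both
groups (no differentiation), one planted site with non-reference allele
probabilities 4/29 vs 24/59, five private mutations per sample, and 5%
per-sample heteroplasmy and homopolymer-indel rates. The generator does
**not** simulate coalescent genealogies, along-genome mutation-rate
heterogeneity, selection, or read-level error; passing recovery tests
therefore demonstrates that the statistics recover the signals they are
defined on, not that they are robust to every artefact of real sequencing
data.

## Validation problem sizes and numerical choices

The validation suites use deliberately scaled problem instances chosen to
exercise the estimators well away from degeneracy while keeping the suite
quick to run: planted-site recovery uses a 2,000-bp genome with 100 + 100
samples, one 0.9-vs-0.3 planted site and 300 null background sites over
100 seeded replicates; interval coverage uses 2,000 null 29/59 tables;
classifier recovery uses a 22-node tree, 500 samples and Poisson(2)
private mutations. Other constants: sample (n−1) SDs everywhere; major
alleles and classifier ties broken alphabetically; permutation p-values
use the (b+1)/(m+1) estimator, which can never return 0; positions are
1-based inclusive throughout, and the genome is treated as circular only
in the gene model.

## Known limitations

* Insertions cannot be represented in the fixed-coordinate consensus
  matrix; VCF insertions are parsed but ignored (with a warning) when
  sequences are reconstructed.
* The classifier is not heteroplasmy-aware and does not weight variants.
* The δ scan's literal 3-SD rule is anticonservative on dense nulls (see
  above); users wanting a null-calibrated screen should use the
  mean-anchored rule or the per-site contingency tests.
* Recomputing t statistics or exact-method confidence intervals from
  rounded published summaries will not reproduce values computed from raw
  data; the package records every method choice in its outputs so such
  discrepancies are traceable.
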