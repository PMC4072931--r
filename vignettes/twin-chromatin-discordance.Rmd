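---
title: "Methods: chromatin discordance analysis in monozygotic twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin discordance analysis in monozygotic twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindisc)
```

## The scientific problem

Monozygotic (MZ) twins share a genome, so any within-pair difference in a
molecular phenotype must arise post-zygotically — from somatic mutation or
from environmentally driven epigenetic divergence. Open-chromatin sequencing
(FAIRE-type enrichment of nucleosome-depleted DNA) measures chromatin
accessibility, a regulatory phenotype that sits immediately upstream of
transcription. `twindisc` implements an integrated analysis of co-twin
*chromatin discordance*: it quantifies accessibility over a common peak
frame, detects somatic mutations and cohort-level polymorphisms directly
from the accessibility reads, relates the mutation spectrum to dinucleotide
context and transcription-factor binding sites (TFBSs), maps *variability
QTLs* — genotypes shared by a pair that predict how *different* the two
siblings are — and couples chromatin discordance to differential expression
and CpG methylation.

Because the real study design (deep targeted sequencing of 72 individuals)
is not reproducible at desk scale, the package is organised around a
synthetic cohort generator with planted ground truth. Every downstream
stage is exercised and validated end-to-end against that truth.

## Accessibility quantification and discordance

Per-sample peak calls are merged into disjoint **meta-peaks** (interval
union; book-ended intervals merge — a deliberate design choice, since two
abutting open regions are one physical locus for quantification purposes).
Accessibility of meta-peak $j$ in sample $i$ is the enrichment of reads
relative to genome background:

$$A_{ji} = \frac{c_{ji} / L_j}{R_i / G},$$

with $c$ the read count, $L_j$ the meta-peak length, $R_i$ the sample's
total mapped reads over meta-peaks (the count-matrix column sum) and $G$
the genome size. The metric is exactly invariant to sequencing depth.
Between-sample distributional differences are then removed by quantile
normalization: each column is mapped onto the row-wise mean of the sorted
columns. Ties receive the *mean* of their tied reference quantiles — a rule
that makes a constant column map to the reference mean. Note a numerical
subtlety: with ties present, this tie rule and exact idempotence cannot hold
simultaneously; on continuous (tie-free) accessibility values the transform
is exactly idempotent, and that is the regime the tests exercise.

Within-pair discordance at a locus with sibling values $X_1, X_2$ is
reported both as $D_{abs} = |X_1 - X_2|$ and the normalized
$D_{norm} = |X_1 - X_2| / (X_1 + X_2) \in [0, 1]$, which avoids the bias of
absolute differences toward highly accessible loci (active promoters,
strong enhancers) when regulatory states are compared. $D_{norm}$ is
undefined (missing) when $X_1 + X_2 = 0$. Discordant sites can be flagged
by effect size — within-pair fold change $> 4$, computed with pseudocount
$c = 1$ on the normalized scale so that near-zero loci do not produce
unbounded ratios (the fold change is evaluated on the quantile-normalized
matrix, i.e. the matrix actually analysed) — or by a variance rule: the
within-pair variance $\frac{1}{n}\sum_p (X_1 - X_2)^2/2$ exceeding the
variance of the pair means, the standard one-way decomposition.

Per-peak values are summarized by regulatory state by interval overlap; a
peak overlapping several state domains contributes to each. Group
contrasts of discordance (mutation present vs absent, TFBS strata) use
two-sided Wilcoxon rank-sum tests, appropriate for a bounded, skewed
quantity.

## Variant calling from allele counts

A **somatic mutation** is a within-pair allele-count difference: at each
position the table [[ref$_1$, alt$_1$], [ref$_2$, alt$_2$]] is tested with a
two-sided Fisher's exact test (minimum-likelihood definition: the sum of
hypergeometric probabilities of tables no more probable than the observed
one; implemented with exact integer weight comparisons whenever the
enumeration fits in double-precision integers). A call requires
$p < 10^{-3}$, at least 10 high-quality reads per strand in *both*
siblings, and — our testable proxy for a "high-confidence" call — the
variant allele on both strands of the carrier with at least 2 reads each.
"High quality" means base quality $\ge 20$; the synthetic data carries this
as per-strand `hq` counts at rate 0.92, matching deep Illumina data.

A **polymorphism** is a cohort-level variant: the position must be covered
in every sample, must not be a somatic call in any pair, and the pooled
minor-allele read fraction must reach 1% (read-weighted across all
samples). Candidates where *every* carrier sample has $> 90\%$ of its
variant reads on one strand are removed as alignment artifacts; the filter
is applied per carrier sample, the stricter of the two readings of "in
each sample". Sex chromosomes are handled only by a contig allow-list.

Base changes are typed only "from the reference homozygote": for mutations
the non-carrier sibling must show zero alternate reads; for polymorphisms
the reference allele must be the major allele (pooled alternate fraction
$\le 0.5$). Typed changes are strand-collapsed into the six classes
C:G>T:A, C:G>A:T, C:G>G:C, A:T>G:C, A:T>C:G, A:T>T:A.

## Dinucleotide spectrum and O/E ratios

The 16 dinucleotides collapse into 10 strand-symmetric classes; the four
palindromes (ApT, CpG, GpC, TpA) are single-member classes and are
double-counted everywhere — in sequence windows and in variant contexts —
so that their counts are commensurate with two-member classes. For each
variant, the two reference-context dinucleotides are tallied: the $-1$
base with the variant base and the variant base with the $+1$ base. The
reference trinucleotide defines the context (changes are typed *from* the
reference).

Enrichment statistics are ratio-of-ratio constructions. Dinucleotide
enrichment in TFBSs relative to background (the host peak minus its TFBS
intervals — chosen so TFBS and background are disjoint — or the whole
genome) is the per-class count ratio normalized by the all-class count
ratio. The substituted-dinucleotide observed/expected ratio divides the
relative enrichment of substitutions by the relative enrichment of the
dinucleotides themselves:

$$OE_d = \frac{(s_d^{T}/s_d^{O}) / (S^{T}/S^{O})}
              {(n_d^{T}/n_d^{O}) / (N^{T}/N^{O})}.$$

All such ratios are exactly 1 on self-comparison (an identity the tests
assert) and ~1 when substitutions are placed uniformly over the sequence;
palindrome double-counting cancels within each class. A CpG-restricted
variant (classes CpG>TpG, CpG>ApG, CpG>GpG) types substitutions at
reference CpGs on either strand, for asking whether 5-methylcytosine
deamination (mCpG>TpG) dominates.

ChIP-defined TFBSs are pre-filtered by summit concentration: the summit is
the position covered by the maximal number of tags (leftmost on ties —
determinism), and a peak is kept only when at least 80% of its tags overlap
the summit, retaining peaks likely to contain a single focused binding
site.

## Variability-QTL mapping

The trait is the pair-level normalized discordance
$y = |X_1 - X_2|/(X_1 + X_2)$ — a *variance* phenotype: a genotype
associated with $y$ marks a locus where siblings sharing that genotype
diverge more, i.e. a genetic-epigenetic interaction. Because most loci
show near-zero within-pair differences, mapping is restricted to the
peaks with the top 1% of between-pair variance in $y$ (ties broken by peak
order; the screen is applied to peaks before and independently of SNP MAF
filtering). For every SNP–peak combination with distance $< 1$ Mb (gap
between the SNP position and the peak interval, 0 inside), $y$ is
regressed on dosage (0/1/2, identical within a pair by MZ design, no
covariates) across pairs with listwise deletion of missing traits;
significance is Benjamini–Hochberg step-up FDR at 0.01 over all tested cis
combinations. One step-up procedure is used for both QTL mapping and the
SNP–accessibility associations (FDR 0.05), keeping multiplicity handling
uniform.

## Expression and methylation integration

Genes are linked to their promoter meta-peak: the nearest peak within
2 kb of the TSS (a parameterized choice — "proximal" has no canonical
width; equidistant ties resolve to the lower coordinate). Within-pair
differential expression is $|\log_2 e_1 - \log_2 e_2|$ on
quantile-normalized log2 intensities (the same normalization code as the
accessibility module). The discordance–expression coupling is tested by
binning observations into discordance tertiles (rank-based, so the bins
are always balanced) and permuting differential expression across
observations; the statistic is the Spearman correlation between tertile
index and differential expression, and the empirical p is
$(b + 1)/(B + 1)$. Gene–pair observations are pooled rather than
stratified by pair — the tertile contrast is a pooled construction — and
the rank statistic makes the p-value invariant to monotone transforms of
the expression differences.

CpG methylation (lymphocyte, ESC, HPC, neutrophil levels in $[0,1]$) is
compared across substitution status: for each CpG the absolute difference
between lymphocyte and each other cell type is computed, and the
distributions for mutated and polymorphic CpGs are each rank-sum-tested
against non-substituted CpGs, optionally after averaging within TFBSs. A
CpG counts as substituted when a variant hits either of its two bases.

## The synthetic cohort: what it emulates, and what it does not

`generate_genome()` builds contigs with a CpG-depleted background (70% of
background CpGs are deaminated to TpG, mimicking the genomic CpG deficit),
disjoint peaks covering a set fraction of the genome, one CpG-enriched
TFBS nested in each peak, state domains labeled with promoter/enhancer
classes, and TSS positions. `generate_twin_cohort()` draws per-peak counts
from a negative binomial with a peak-level lognormal intensity, a
pair-level lognormal random effect (twin correlation exceeding
unrelated-sample correlation), and a per-sample depth factor — the
simplest model with the required covariance structure. Allele counts are
binomial thinnings of a Poisson position depth with strands split
Binomial(n, 1/2), making the strand filters testable.

Default study conditions (fixed once, not tuned): 36 twin pairs; one 1 Mb
contig with ~300 peaks of 100–200 bp (4.5% of the genome — the peak count
of the emulated design takes precedence over its 2% coverage, which cannot
hold simultaneously at realistic peak sizes); mean 200 reads per peak,
dispersion 0.05; variant-position depth Poisson(72), matching deep
targeted coverage; sequencing error 0.002 and high-quality fraction 0.92;
20 planted mutations (VAF 0.5 in one sibling, 70% decreasing the carrier's
host-peak accessibility, factor 0.4, vs factor 2.2 for increases); 30
polymorphisms at population allele frequencies 0.1–0.4; 3 planted
variability QTLs at MAF 0.1–0.5 with `qtl_beta = 0.3` — one sibling's peak
mean is scaled by $(1+t)/(1-t)$, $t = \beta \cdot g$, so the expected
normalized discordance shifts by $\beta$ per dosage unit. $\beta = 0.3$ is
sized so that a planted locus's between-pair discordance variance
dominates the top-1% variance screen even at the low end of the MAF range;
with 3 planted QTLs and a top-1% screen keeping 3 of ~300 peaks, recovery
requires exactly that dominance. Expression couples
$|\Delta\log_2 e| = 1.5 \cdot D_{norm}$ at linked promoters with 0.25
log2 units of noise; methylation gives regulated CpGs a lymphocyte–ESC
difference centered on `delta` (HPC intermediate at 0.6·delta, neutrophil —
a differentiated lineage — at 0.25·delta), clipped to $[0,1]$.

What the generator does **not** emulate: read-level artifacts
(mappability, GC bias, PCR duplicates), linkage disequilibrium between
SNPs, cell-population heterogeneity, trans effects, indels or
multi-allelic sites, and sex chromosomes. Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under the declared generative model, not robustness to alignment-level
confounders of real data.

## Numerical choices

* Fisher p-values: exact integer comparison of enumeration weights where
  products stay below $2^{53}$; log-space with relative tolerance
  $10^{-7}$ beyond (the conventional safeguard against floating-point
  ties). Degenerate margins give $p = 1$.
* All randomness flows from explicit seeds through one helper that
  restores the caller's RNG state; stage seeds are derived from the run
  seed. Identical seeds give byte-identical outputs.
* Tie-breaks are deterministic everywhere: leftmost ChIP summit, lower
  coordinate for equidistant promoter peaks, stable peak order in the
  variance screen.
* Problem sizes in the test-suite simulations (replicate counts, position
  counts, permutation counts) are the package's chosen verification scale:
  large enough for the stated calibration bounds, small enough to run
  interactively.

## Known limitations

* The fold-change discordance rule depends on the pseudocount at
  low-accessibility loci; the default $c = 1$ (on the normalized scale) is
  a conventional, not estimated, choice.
* The variability-QTL screen conditions on high between-pair variance;
  effect estimates at selected loci are subject to selection (winner's
  curse) and should be interpreted as a discovery set.
* The permutation test pools gene–pair observations; within-gene
  correlation across pairs is not modeled under the null, which is exact
  only under exchangeability of observations.
* Polymorphism genotype dosages inferred from pooled read fractions
  (thresholds 0.25/0.75) are a coarse stand-in for array genotypes and
  will misclassify at allele-specific accessibility sites.
* With few planted QTLs and a top-1% screen keeping a similarly small
  number of loci, end-to-end QTL recovery is all-or-nothing per locus: a
  planted effect drawn near the bottom of the MAF range can rank just
  below the variance-screen cutoff at 36 pairs, so recovery across
  arbitrary simulation seeds fluctuates rather than sitting at 100%.

## Running the pipeline

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
manifest <- run_pipeline(cfg, out_dir = "run1")
str(manifest$stages)
```

The run directory contains every stage's inputs and outputs as flat files
(`sim/` for the generated cohort and its `truth/`, then
`accessibility.tsv`, `discordance.tsv`, `mutations.vcf`,
`polymorphisms.vcf`, `dinuc_enrichment.tsv`, `qtl_associations.tsv`,
`expression_coupling.tsv`, `methylation_summary.tsv`, and a
`manifest.json` recording the config hash, seed, and per-stage row
counts). Re-running the same config reproduces the manifest byte for
byte.
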