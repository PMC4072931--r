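# twindisc

Chromatin-accessibility discordance analysis for monozygotic (MZ) twin
cohorts.

MZ twins share a genome, so within-pair differences in a molecular
phenotype must arise post-zygotically. `twindisc` analyses co-twin
discordance in open-chromatin (FAIRE-seq style) accessibility and its
genetic correlates, end to end:

* **Accessibility quantification** over merged meta-peaks,
  `A = (c/L)/(R/G)` (read count per bp, calibrated by total reads over
  genome size), followed by quantile normalization; within-pair
  discordance `D_norm = |X1 − X2|/(X1 + X2)`, with fold-change and
  variance-decomposition rules for flagging discordant sites and
  regulatory-state summaries.
* **Somatic mutation calling** (within-pair differences) from
  strand-resolved allele read counts by two-sided Fisher's exact test
  (`p < 1e-3`, ≥ 10 high-quality reads per strand per sibling, variant on
  both carrier strands), and **polymorphism calling** (cohort variants at
  pooled minor-allele frequency ≥ 1%, covered in all samples, one-strand
  artifact filter).
* **Mutation-spectrum statistics**: strand-collapsed base-change classes,
  dinucleotide-context spectra with palindrome double-counting, and
  observed/expected ratio-of-ratio enrichments of substituted
  dinucleotides in transcription-factor binding sites (TFBSs) — the
  statistic behind CpG substitution depletion — plus ChIP peak summit
  filtering.
* **Variability-QTL mapping**: genotypes shared by a pair associated with
  the pair's normalized discordance (a variance phenotype) by simple
  linear regression over the top-variance loci, cis window 1 Mb,
  step-up FDR.
* **Integration**: promoter-linked differential expression vs chromatin
  discordance (tertile rank statistic, 10,000 permutations) and CpG
  methylation differences across cell types by substitution status.
* **Synthetic cohort generator** with planted ground truth (mutations,
  polymorphisms, QTLs, expression coupling, regulated CpGs), so the whole
  pipeline is testable without any external data.

See the methods vignette
(`vignettes/twin-chromatin-discordance.Rmd`) for the models, parameter
defaults, and design rationale.

## Worked example

```r
library(twindisc)

a  <- generate_genome(contig_length = 2e5, seed = 1)
a
#> Synthetic genome: 1 contig(s), 2e+05 bp; 60 peaks (4.66% of genome), 60 TFBSs, 2510 CpGs, 60 genes

co <- generate_twin_cohort(a, n_pairs = 12, n_mutations = 8, n_qtls = 1, seed = 2)
co
#> Synthetic twin cohort: 12 pairs, 60 peaks, 188 allele positions, 51 SNPs
#> Planted truth: 8 mutations, 30 polymorphisms, 1 QTLs

A    <- quantile_normalize(normalize_accessibility(co$counts, a$peaks, a$genome_size))
disc <- pair_discordance(A, co$pairing)
muts <- call_somatic_mutations(co$alleles, co$pairing)
head(muts[, c("chrom", "pos", "ref", "alt", "pair_id", "carrier", "p_value")], 4)
#>   chrom   pos ref alt pair_id carrier      p_value
#> 1  chr1 36055   T   A  pair09       2 2.564673e-13
#> 2  chr1 58770   T   C  pair07       1 1.821490e-12
#> 3  chr1 72150   G   C  pair10       1 1.730197e-14
#> 4  chr1 86524   A   C  pair08       1 1.298930e-10
```

All 8 planted mutations are recovered at the default thresholds. Loci
carrying a planted mutation are markedly more discordant than background:

```r
compare_discordance_by_group(
  disc$d_norm,
  ifelse(paste(disc$peak_id, disc$pair_id) %in%
           paste(co$truth$mutations$peak_id, co$truth$mutations$pair_id),
         "mutated", "background"))
#> $means
#> background    mutated
#>  0.1301754  0.4084434
#>
#> $tests
#>     group            p
#> 1 mutated 0.0005906813
```

The mean normalized discordance at mutated (peak, pair) observations is
0.41 vs 0.13 at background loci (rank-sum p ≈ 6e-4): planted somatic
mutations produce exactly the discordance signal the pipeline is designed
to detect.

The full pipeline — simulation through integration, with every stage
coupled by flat files and a reproducible manifest — is one call:

```r
manifest <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

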