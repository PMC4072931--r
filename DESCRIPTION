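Package: twindisc
Title: Chromatin Accessibility Discordance Analysis for Monozygotic Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies open-chromatin (FAIRE-seq style) accessibility over
    meta-peaks, measures within-pair discordance between monozygotic twin
    siblings, calls somatic mutations and polymorphisms from strand-resolved
    allele read counts by Fisher's exact test, computes dinucleotide-context
    observed-to-expected mutation-spectrum ratios in transcription factor
    binding sites, maps variability QTLs (genotypes associated with the
    magnitude of within-pair differences), and couples chromatin discordance
    to differential expression and CpG methylation. Ships a fully synthetic
    twin-cohort generator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    vcfR,
    withr
Config/testthat/edition: 3
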