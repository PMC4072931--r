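test_that("genome generation is deterministic and respects its contracts", {
  a1 <- generate_genome(contig_length = 1e5, peak_density = 0.02, seed = 5)
  a2 <- generate_genome(contig_length = 1e5, peak_density = 0.02, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1, generate_genome(contig_length = 1e5, peak_density = 0.02, seed = 6)))
  # peak coverage within +/- 20% of the target density
  big <- generate_genome(contig_length = 1e6, peak_density = 0.02, seed = 7)
  bp <- sum(big$peaks$end - big$peaks$start)
  expect_gte(bp, 16000); expect_lte(bp, 24000)
  # every TFBS nested in exactly one peak
  hp <- GenomicRanges::findOverlaps(
    twindisc:::as_granges0(a1$tfbs), twindisc:::as_granges0(a1$peaks),
    type = "within")
  expect_equal(length(hp), nrow(a1$tfbs))
  expect_false(anyDuplicated(S4Vectors::queryHits(hp)) > 0)
  # cpg_positions exactly the CG occurrences of the sequence
  s <- a1$sequences[["chr1"]]
  v <- strsplit(s, "")[[1]]
  expect_equal(a1$cpg_positions$pos, which(v[-length(v)] == "C" & v[-1] == "G") - 1L)
  expect_true(all(c("poised promoter", "active promoter") %in%
                    c(a1$states$name, big$states$name)))
  expect_error(generate_genome(contig_length = 5000), ">= 10,000")
  expect_error(generate_genome(peak_density = 0.2), "peak_density")
})

test_that("TFBS CpG enrichment meets the requested boost, measured from the assets", {
  a <- generate_genome(contig_length = 3e5, peak_density = 0.04,
                       tfbs_cpg_boost = 4, seed = 13)
  cpg_freq <- function(regions) {
    sp <- count_sequence_dinucleotides(a$sequences, regions)
    unname(sp["CpG"] / sum(sp))
  }
  open_bg <- twindisc:::open_minus_tfbs(a$peaks, a$tfbs)
  expect_gte(cpg_freq(a$tfbs[, c("chrom", "start", "end")]) / cpg_freq(open_bg), 4)
})

test_that("cohort generation plants recoverable mutations with the declared allele model", {
  a <- generate_genome(contig_length = 1e5, seed = 1)
  co <- generate_twin_cohort(a, n_pairs = 36, n_mutations = 10, n_qtls = 1,
                             allele_depth = 30, error_rate = 0, seed = 2)
  expect_equal(ncol(co$counts), 72)
  expect_identical(co$counts,
                   generate_twin_cohort(a, n_pairs = 36, n_mutations = 10, n_qtls = 1,
                                        allele_depth = 30, error_rate = 0, seed = 2)$counts)
  # siblings share genotype dosages exactly by construction (pair-level matrix)
  expect_equal(nrow(co$genotypes), 36)
  al <- co$alleles
  tr <- co$truth$mutations
  for (i in seq_len(nrow(tr))) {
    rows <- al[al$chrom == tr$chrom[i] & al$pos == tr$pos[i], ]
    carrier <- paste0(tr$pair_id[i], "_", tr$carrier[i])
    other <- paste0(tr$pair_id[i], "_", 3 - tr$carrier[i])
    ca <- rows[rows$sample == carrier, ]
    expect_gt(ca$fwd_alt + ca$rev_alt, 0)
    ot <- rows[rows$sample == other, ]
    # with zero error rate the non-carrier shows no alternate reads
    expect_equal(ot$fwd_alt + ot$rev_alt, 0)
  }
  # carrier alt fraction consistent with VAF 0.5 across planted sites
  ca_all <- merge(al, data.frame(chrom = tr$chrom, pos = tr$pos,
                                 sample = paste0(tr$pair_id, "_", tr$carrier)))
  f <- sum(ca_all$fwd_alt + ca_all$rev_alt) /
    sum(ca_all$fwd_alt + ca_all$rev_alt + ca_all$fwd_ref + ca_all$rev_ref)
  expect_gt(f, 0.35); expect_lt(f, 0.65)
  expect_error(generate_twin_cohort(a, n_pairs = 1), "n_pairs")
  expect_error(generate_twin_cohort(a, n_mutations = 1e7), "exceeds")
})

test_that("null planted-QTL effects are indistinguishable from background discordance", {
  a <- generate_genome(contig_length = 1e5, seed = 3)
  qtl_d <- c(); bg_d <- c()
  for (r in 1:20) {
    co <- generate_twin_cohort(a, n_pairs = 8, n_mutations = 0, n_qtls = 2,
                               qtl_beta = 0, seed = 100 + r)
    A <- quantile_normalize(normalize_accessibility(co$counts, a$peaks, a$genome_size))
    disc <- pair_discordance(A, co$pairing)
    planted <- disc$peak_id %in% co$truth$qtls$peak_id
    qtl_d <- c(qtl_d, disc$d_norm[planted])
    bg_d <- c(bg_d, disc$d_norm[!planted])
  }
  expect_gt(wilcox.test(qtl_d, bg_d)$p.value, 0.01)
})

test_that("expression coupling follows the requested slope and vanishes at zero", {
  a <- generate_genome(contig_length = 2e6, peak_density = 0.05, seed = 4)
  co <- generate_twin_cohort(a, n_pairs = 6, n_mutations = 20, n_qtls = 2, seed = 5)
  # coupling 0: gene-wise |delta expr| uncorrelated with discordance
  ex0 <- generate_expression(co, a, coupling_strength = 0, seed = 6)
  A <- quantile_normalize(normalize_accessibility(co$counts, a$peaks, a$genome_size))
  disc <- pair_discordance(A, co$pairing)
  de <- within_pair_expression_diff(ex0$expression, co$pairing)
  links <- link_genes_to_peaks(a$tss, a$peaks)
  dmean <- tapply(disc$d_norm, disc$peak_id, mean, na.rm = TRUE)
  gd <- dmean[links$peak_id]
  ge <- rowMeans(de)[links$gene_id]
  expect_gte(length(gd), 400)
  expect_lt(abs(cor(gd, ge, use = "complete")), 0.1)
  # positive coupling is detectable
  ex1 <- generate_expression(co, a, coupling_strength = 2, seed = 6)
  de1 <- within_pair_expression_diff(ex1$expression, co$pairing)
  ge1 <- rowMeans(de1)[links$gene_id]
  expect_gt(cor(gd, ge1, use = "complete"), 0.3)
  # identical sibling accessibility and zero noise: delta expression is 0
  co2 <- co
  s1 <- twindisc:::sibling_samples(co$pairing, 1)
  s2 <- twindisc:::sibling_samples(co$pairing, 2)
  co2$counts[, s2] <- co2$counts[, s1]
  ex2 <- generate_expression(co2, a, coupling_strength = 2, noise_sd = 0, seed = 7)
  de2 <- within_pair_expression_diff(ex2$expression, co2$pairing)
  expect_equal(max(abs(de2)), 0, tolerance = 1e-12)
  # determinism
  expect_identical(ex1$expression,
                   generate_expression(co, a, coupling_strength = 2, seed = 6)$expression)
})

test_that("methylation profiles respect delta, clipping and the regulated flag", {
  a <- generate_genome(contig_length = 2e5, seed = 8)
  me <- generate_methylation(a, regulated_fraction = 0.5, delta = 0.8, seed = 9)
  m <- me$methylation
  for (ct in c("lymphocyte", "ESC", "HPC", "neutrophil")) {
    expect_true(all(m[[ct]] >= 0 & m[[ct]] <= 1))
  }
  reg <- me$truth$regulated
  d <- abs(m$lymphocyte - m$ESC)
  expect_gte(mean(d[reg]), 0.7); expect_lte(mean(d[reg]), 0.8)
  expect_lt(mean(d[!reg]), 0.1)
  none <- generate_methylation(a, regulated_fraction = 0, delta = 0.5, seed = 9)
  expect_false(any(none$truth$regulated))
  expect_error(generate_methylation(a, delta = 1.5), "delta")
})
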