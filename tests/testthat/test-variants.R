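test_that("two-sided Fisher p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  # [[10,0],[0,10]]: only the two extreme tables are as improbable
  expect_equal(fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(0, 2, 2)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(5)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_two_sided(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact_two_sided(tb),
                 fisher_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("somatic mutation calling applies the p, high-quality and strand filters", {
  pairing <- make_pairing(1)
  # sibling1 20 ref / 0 alt, sibling2 2 ref / 18 alt, strand-balanced, hq ok
  al <- pair_alleles(pos = 100, ref1 = 20, alt1 = 0, ref2 = 2, alt2 = 18, hq = 12)
  calls <- call_somatic_mutations(al, pairing)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$carrier, 2L)
  expect_equal(calls$p_value, fisher_oracle(20, 0, 2, 18), tolerance = 1e-12)
  expect_lt(calls$p_value, 1e-3)
  # 9 high-quality reads on one strand in one sibling: rejected regardless of p
  al9 <- al; al9$hq_fwd[1] <- 9
  expect_equal(nrow(call_somatic_mutations(al9, pairing)), 0)
  # identical counts in both siblings: p = 1, not called
  same <- pair_alleles(pos = 200, ref1 = 10, alt1 = 10, ref2 = 10, alt2 = 10, hq = 15)
  expect_equal(nrow(call_somatic_mutations(same, pairing)), 0)
  # carrier must show the variant on both strands
  onestr <- pair_alleles(pos = 300, ref1 = 20, alt1 = 0, ref2 = 2, alt2 = 18, hq = 12)
  onestr$fwd_alt[2] <- 18; onestr$rev_alt[2] <- 0
  expect_equal(nrow(call_somatic_mutations(onestr, pairing)), 0)
})

test_that("mutation calling is symmetric under sibling relabeling", {
  pairing <- make_pairing(2)
  set.seed(9)
  al <- rbind(
    pair_alleles(pos = 10, ref1 = 25, alt1 = 0, ref2 = 12, alt2 = 14, pair = "p1", hq = 12),
    pair_alleles(pos = 20, ref1 = 10, alt1 = 16, ref2 = 28, alt2 = 0, pair = "p1", hq = 13),
    pair_alleles(pos = 10, ref1 = 22, alt1 = 1, ref2 = 24, alt2 = 0, pair = "p2", hq = 11)
  )
  fwd <- call_somatic_mutations(al, pairing)
  swapped <- al
  swapped$sample <- ifelse(grepl("_1$", al$sample),
                           sub("_1$", "_2", al$sample), sub("_2$", "_1", al$sample))
  rev <- call_somatic_mutations(swapped, pairing)
  expect_equal(fwd[, c("chrom", "pos", "pair_id", "p_value")],
               rev[, c("chrom", "pos", "pair_id", "p_value")])
  expect_equal(fwd$carrier, 3L - rev$carrier)
})

test_that("polymorphism calling enforces coverage, pooled MAF boundary and strand filter", {
  pairing <- make_pairing(2)
  mk <- function(pos, alt_by_sample, tot = 250, one_strand = FALSE) {
    do.call(rbind, lapply(seq_along(pairing$sample_id), function(i) {
      a <- alt_by_sample[i]
      fa <- if (one_strand) a else floor(a / 2)
      allele_row(pos = pos, sample = pairing$sample_id[i],
                 fwd_ref = floor((tot - a) / 2), rev_ref = ceiling((tot - a) / 2),
                 fwd_alt = fa, rev_alt = a - fa)
    }))
  }
  # 4 samples x 250 reads = 1000; 10 alt reads -> pooled MAF exactly 0.01
  al <- rbind(mk(1, c(10, 0, 0, 0)),      # maf = 0.01 -> retained
              mk(2, c(9, 0, 0, 0)),       # maf = 0.009 -> excluded
              mk(3, c(40, 40, 0, 0), one_strand = TRUE),  # strand-biased carriers
              mk(4, c(0, 0, 0, 0)))       # no variant
  calls <- call_polymorphisms(al, pairing)
  expect_equal(calls$pos, 1)
  expect_equal(calls$pooled_maf, 0.01)
  # zero coverage in one sample excludes the position
  cov0 <- mk(5, c(100, 0, 0, 0))
  cov0[cov0$sample == "p2_2", c("fwd_ref", "rev_ref", "fwd_alt", "rev_alt")] <- 0
  expect_equal(nrow(call_polymorphisms(cov0, pairing)), 0)
  # somatic positions are excluded
  som <- data.frame(chrom = "chr1", pos = 1)
  expect_equal(nrow(call_polymorphisms(al, pairing, somatic_calls = som)), 0)
  # one balanced carrier rescues a position from the strand filter
  biased <- mk(6, c(40, 40, 0, 0), one_strand = TRUE)
  balanced_second <- mk(6, c(40, 40, 0, 0), one_strand = FALSE)
  mixed <- rbind(biased[biased$sample != "p1_2", ],
                 balanced_second[balanced_second$sample == "p1_2", ])
  expect_equal(call_polymorphisms(mixed, pairing)$pos, 6)
  contig <- call_polymorphisms(al, pairing, contigs = "chrX")
  expect_equal(nrow(contig), 0)
})

test_that("base changes collapse strands and respect reference-homozygote gating", {
  expect_equal(base_change_class("C", "A"), "C:G>A:T")
  expect_equal(base_change_class("G", "A"), "C:G>T:A")  # complement of C>T
  expect_equal(base_change_class("A", "G"), "A:T>G:C")
  expect_equal(base_change_class("T", "A"), "A:T>T:A")
  expect_error(base_change_class("N", "A"), "A/C/G/T")
  muts <- data.frame(chrom = "chr1", pos = c(1, 2), ref = c("C", "C"), alt = c("A", "T"),
                     class = "somatic_mutation", other_alt = c(0, 5))
  typed <- classify_base_change(muts)
  expect_equal(typed$base_change, c("C:G>A:T", NA))  # het non-carrier -> unclassified
  pol <- data.frame(chrom = "chr1", pos = 1:2, ref = "G", alt = "T",
                    class = "polymorphism", pooled_alt_frac = c(0.2, 0.8))
  tp <- classify_base_change(pol)
  expect_equal(tp$base_change, c("C:G>A:T", NA))
})

test_that("mutation peak context gives center distances and densities", {
  peaks <- data.frame(peak_id = c("pk1", "pk2"), chrom = "chr1",
                      start = c(100, 1000), end = c(300, 1200))
  calls <- data.frame(chrom = "chr1", pos = c(150, 200, 110, 205, 5000),
                      pair_id = "p1")
  expect_message(ctx <- annotate_mutation_peak_context(calls, peaks), "outside")
  expect_equal(ctx$calls$dist_to_center, c(50, 0, 90, 5, NA))
  dens <- ctx$peak_density
  expect_equal(dens$peak_id, "pk1")
  expect_equal(dens$mutations_per_bp, 4 / 200)
  # 3 mutations in a 200 bp peak -> 0.015 / bp
  calls3 <- data.frame(chrom = "chr1", pos = c(150, 160, 170))
  expect_equal(annotate_mutation_peak_context(calls3, peaks)$peak_density$mutations_per_bp,
               0.015)
})

test_that("SNP-accessibility association is calibrated and finds perfect fits", {
  peaks <- data.frame(peak_id = sprintf("pk%d", 1:2), chrom = "chr1",
                      start = c(0, 1000), end = c(500, 1500))
  samples <- sprintf("s%d", 1:12)
  g <- matrix(rep(c(0, 1, 2), each = 4), 1, dimnames = list("snp1", samples))
  A <- matrix(0, 2, 12, dimnames = list(peaks$peak_id, samples))
  A["pk1", ] <- 1 + 0.5 * g[1, ]   # exactly linear, zero residual
  pos <- data.frame(chrom = "chr1", pos = 10)
  res <- associate_snp_accessibility(g, pos, A, peaks)
  expect_true(res$significant)
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
  # constant dosage -> skipped with warning
  gc <- matrix(1, 1, 12, dimnames = list("snp1", samples))
  expect_warning(res2 <- associate_snp_accessibility(gc, pos, A, peaks), "constant dosage")
  expect_false(res2$significant)
  # global null: fraction with p < 0.05 near nominal
  set.seed(31)
  n_snp <- 1000
  gN <- matrix(rbinom(n_snp * 12, 2, 0.4), n_snp, 12,
               dimnames = list(sprintf("s%d", 1:n_snp), samples))
  AN <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(peaks$peak_id, samples))
  posN <- data.frame(chrom = "chr1", pos = rep(10, n_snp))
  suppressWarnings(resN <- associate_snp_accessibility(gN, posN, AN, peaks))
  frac <- mean(resN$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("closed-form OLS matches stats::lm", {
  set.seed(17)
  x <- rbinom(30, 2, 0.4); y <- 0.2 * x + rnorm(30, 0, 0.3)
  fit <- twindisc:::ols_slope_test(x, y)
  lmfit <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$slope, lmfit["x", "Estimate"], tolerance = 1e-12)
  expect_equal(fit$t, lmfit["x", "t value"], tolerance = 1e-12)
  expect_equal(fit$p, lmfit["x", "Pr(>|t|)"], tolerance = 1e-12)
})
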