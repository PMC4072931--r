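## Synthetic twin-cohort generator. Defaults emulate the study design the
## package targets: 36 monozygotic pairs, ~300 open-chromatin peaks on a 1 Mb
## genome (~4.5% coverage), deep targeted coverage (~72x) at variant
## positions, CpG-enriched TFBSs nested in peaks, negative-binomial peak
## counts with a pair-level random effect, and planted ground truth
## (mutations, polymorphisms, variability QTLs) recoverable from the emitted
## files alone.

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic genome with peaks, TFBSs and regulatory states
#'
#' Builds random contigs with a CpG-depleted background (mimicking the
#' deamination-driven CpG deficit of real genomes), disjoint open-chromatin
#' peaks covering `peak_density` of the genome, one CpG-enriched TFBS nested
#' inside each peak, labeled regulatory-state domains around the peaks
#' (including poised and active promoters), and per-gene TSS positions.
#'
#' @param n_contigs number of contigs (default 1).
#' @param contig_length contig length in bp (>= 10 kb).
#' @param peak_density target fraction of the genome covered by peaks
#'   (0 < density <= 0.05).
#' @param tfbs_cpg_boost minimum fold-enrichment of CpG frequency in TFBSs
#'   over non-TFBS open chromatin (>= 1); the generator plants CpGs with a
#'   1.6x safety margin over this target.
#' @param peak_len_range,tfbs_len_range min/max lengths in bp.
#' @param seed RNG seed; identical seeds give byte-identical assets.
#'
#' @return list of class `genome_assets`: `sequences` (named character),
#'   `genome_size`, `peaks`, `tfbs`, `states` (with `name` labels),
#'   `cpg_positions` (`chrom`, `pos`, 0-based), `tss`.
#' @export
generate_genome <- function(n_contigs = 1, contig_length = 1e6,
                            peak_density = 0.045, tfbs_cpg_boost = 4,
                            peak_len_range = c(100, 200),
                            tfbs_len_range = c(12, 30), seed = 1) {
  if (contig_length < 1e4) stopf("contig_length must be >= 10,000")
  if (!(peak_density > 0 && peak_density <= 0.05)) stopf("peak_density must be in (0, 0.05]")
  if (tfbs_cpg_boost < 1) stopf("tfbs_cpg_boost must be >= 1")
  with_rng(seed, {
    base_prob <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    cpg_deplete <- 0.7
    # expected background CpG window frequency after depletion
    f_bg <- (1 - cpg_deplete) * base_prob["C"] * base_prob["G"]
    q_cpg <- min(0.9, 2 * 1.6 * tfbs_cpg_boost * as.numeric(f_bg))

    sequences <- character(n_contigs)
    names(sequences) <- sprintf("chr%d", seq_len(n_contigs))
    peaks <- list(); tfbs <- list(); states <- list(); tss <- list(); cpgs <- list()
    state_levels <- c("active promoter", "poised promoter", "strong enhancer",
                      "weak enhancer", "insulator", "transcribed")
    state_prob <- c(0.15, 0.10, 0.20, 0.25, 0.10, 0.20)

    for (ci in seq_len(n_contigs)) {
      chrom <- names(sequences)[ci]
      L <- as.integer(contig_length)
      v <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
      cg <- which(v[-L] == "C" & v[-1] == "G")
      dep <- cg[runif(length(cg)) < cpg_deplete]
      v[dep] <- "T"

      mean_len <- mean(peak_len_range)
      n_peaks <- max(1L, round(peak_density * L / mean_len))
      slot <- floor(L / n_peaks)
      if (slot <= peak_len_range[2] + 40) stopf("peak_density too high for the peak length range")
      plen <- round(runif(n_peaks, peak_len_range[1], peak_len_range[2]))
      off <- floor(runif(n_peaks, 20, slot - plen - 20))
      pstart <- (seq_len(n_peaks) - 1L) * slot + off
      pend <- pstart + plen

      tlen <- round(runif(n_peaks, tfbs_len_range[1], min(tfbs_len_range[2], peak_len_range[1] - 2)))
      toff <- floor(runif(n_peaks, 0, plen - tlen))
      tstart <- pstart + toff
      tend <- tstart + tlen

      # CpG-enriched TFBS sequence: emit "CG" blocks at rate q_cpg
      for (k in seq_len(n_peaks)) {
        n2 <- ceiling(tlen[k] / 2)
        use_cg <- runif(n2) < q_cpg
        blocks <- character(n2)
        blocks[use_cg] <- "CG"
        n_other <- sum(!use_cg)
        if (n_other) {
          blocks[!use_cg] <- paste0(
            sample(names(base_prob), n_other, TRUE, base_prob),
            sample(names(base_prob), n_other, TRUE, base_prob))
        }
        tseq <- strsplit(paste(blocks, collapse = ""), "")[[1]][seq_len(tlen[k])]
        v[(tstart[k] + 1):(tstart[k] + tlen[k])] <- tseq
      }
      sequences[ci] <- paste(v, collapse = "")

      peaks[[ci]] <- data.frame(chrom = chrom, start = pstart, end = pend,
                                stringsAsFactors = FALSE)
      tfbs[[ci]] <- data.frame(chrom = chrom, start = tstart, end = tend,
                               stringsAsFactors = FALSE)

      dom <- merge_peaks(data.frame(chrom = chrom,
                                    start = pmax(0, pstart - 500),
                                    end = pmin(L, pend + 500)))
      states[[ci]] <- data.frame(chrom = chrom, start = dom$start, end = dom$end,
                                 name = sample(state_levels, nrow(dom), TRUE, state_prob),
                                 stringsAsFactors = FALSE)

      has_gene <- runif(n_peaks) < 0.8
      g_in <- data.frame(chrom = chrom,
                         pos = pstart[has_gene] +
                           floor(runif(sum(has_gene), 0, plen[has_gene])),
                         stringsAsFactors = FALSE)
      n_bg_genes <- round(0.15 * n_peaks)
      g_bg <- data.frame(chrom = chrom,
                         pos = sort(sample.int(L, n_bg_genes)) - 1L,
                         stringsAsFactors = FALSE)
      tss[[ci]] <- rbind(g_in, g_bg)

      vv <- strsplit(sequences[ci], "")[[1]]
      cpgs[[ci]] <- data.frame(chrom = chrom,
                               pos = which(vv[-L] == "C" & vv[-1] == "G") - 1L,
                               stringsAsFactors = FALSE)
    }

    peaks <- do.call(rbind, peaks)
    peaks <- cbind(peak_id = sprintf("peak_%04d", seq_len(nrow(peaks))), peaks,
                   stringsAsFactors = FALSE)
    peaks$length <- peaks$end - peaks$start
    tfbs <- do.call(rbind, tfbs)
    tfbs <- cbind(tfbs_id = sprintf("tfbs_%04d", seq_len(nrow(tfbs))), tfbs,
                  stringsAsFactors = FALSE)
    tss <- do.call(rbind, tss)
    tss <- cbind(gene_id = sprintf("gene_%04d", seq_len(nrow(tss))), tss,
                 stringsAsFactors = FALSE)
    tss$strand <- sample(c("+", "-"), nrow(tss), TRUE)

    structure(list(
      sequences = sequences,
      genome_size = n_contigs * as.integer(contig_length),
      peaks = peaks, tfbs = tfbs,
      states = do.call(rbind, states),
      cpg_positions = do.call(rbind, cpgs),
      tss = tss
    ), class = "genome_assets")
  })
}

#' @export
print.genome_assets <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d contig(s), %s bp; %d peaks (%.2f%% of genome), %d TFBSs, %d CpGs, %d genes\n",
              length(x$sequences), format(x$genome_size, big.mark = ","),
              nrow(x$peaks), 100 * sum(x$peaks$end - x$peaks$start) / x$genome_size,
              nrow(x$tfbs), nrow(x$cpg_positions), nrow(x$tss)))
  invisible(x)
}

#' Generate a synthetic twin cohort with planted ground truth
#'
#' Simulates per-peak read counts for `2 * n_pairs` samples with a
#' negative-binomial model (peak-level lognormal intensity, pair-level
#' lognormal random effect creating twin correlation, sample-level depth
#' factor), strand-resolved allele read counts at planted somatic-mutation,
#' polymorphism and null positions, and pair-shared SNP dosages with planted
#' cis variability-QTL effects on the normalized within-pair discordance.
#'
#' Planted mutations sit inside TFBSs, appear as alternate-allele reads
#' (VAF 0.5) in exactly one sibling with strand-balanced counts, and scale
#' the carrier's host-peak accessibility (decrease in 70% of cases, matching
#' the predominance of accessibility-reducing mutations). At a planted-QTL
#' locus one sibling's peak mean is scaled so the expected normalized
#' discordance shifts by `qtl_beta` per dosage unit.
#'
#' @param assets a `genome_assets` object.
#' @param n_pairs number of twin pairs (>= 2; default 36).
#' @param depth mean reads per peak per sample (default 200).
#' @param dispersion negative-binomial overdispersion (var = mu + dispersion
#'   * mu^2; default 0.05).
#' @param n_mutations planted somatic mutations (default 20; must not exceed
#'   the available TFBS positions).
#' @param n_qtls planted cis variability-QTLs (default 3).
#' @param qtl_beta shift in expected normalized discordance per dosage unit
#'   (default 0.3).
#' @param allele_depth mean read depth at variant positions (default 72).
#' @param error_rate per-read sequencing error rate (default 0.002).
#' @param hq_rate fraction of reads that are high-quality (default 0.92).
#' @param n_background_snps null SNPs in the genotype matrix (default 50).
#' @param n_polymorphisms planted polymorphisms (default 30).
#' @param n_null_positions variant-free allele-count positions (default 150).
#' @param mutation_vaf variant allele fraction in the carrier (default 0.5).
#' @param seed RNG seed.
#'
#' @return list of class `twin_cohort_sim`: `pairing` ([twin_cohort()]),
#'   `counts` (peak x sample integer matrix), `alleles`, `genotypes`
#'   (pair x SNP dosage matrix), `snp_positions`, and `truth` (data.frames
#'   `mutations`, `polymorphisms`, `qtls`).
#' @export
generate_twin_cohort <- function(assets, n_pairs = 36, depth = 200,
                                 dispersion = 0.05, n_mutations = 20,
                                 n_qtls = 3, qtl_beta = 0.3,
                                 allele_depth = 72, error_rate = 0.002,
                                 hq_rate = 0.92, n_background_snps = 50,
                                 n_polymorphisms = 30, n_null_positions = 150,
                                 mutation_vaf = 0.5, seed = 1) {
  if (n_pairs < 2) stopf("n_pairs must be >= 2")
  if (depth <= 0) stopf("depth must be positive")
  tf <- assets$tfbs
  tfbs_bp <- sum(tf$end - tf$start)
  if (n_mutations > tfbs_bp) stopf("n_mutations (%d) exceeds available TFBS positions (%d)", n_mutations, tfbs_bp)

  with_rng(seed, {
    peaks <- assets$peaks
    m <- nrow(peaks)
    pair_id <- sprintf("pair%02d", seq_len(n_pairs))
    samples <- as.vector(rbind(paste0(pair_id, "_1"), paste0(pair_id, "_2")))
    pairing <- twin_cohort(samples, rep(pair_id, each = 2), rep(1:2, n_pairs))

    peak_int <- rlnorm(m, 0, 0.5)
    pair_eff <- matrix(rlnorm(m * n_pairs, 0, 0.3), m, n_pairs)
    depth_fac <- rlnorm(2 * n_pairs, 0, 0.2)
    mu <- matrix(0, m, 2 * n_pairs, dimnames = list(peaks$peak_id, samples))
    for (p in seq_len(n_pairs)) {
      for (s in 1:2) {
        mu[, 2 * (p - 1) + s] <- depth * peak_int * pair_eff[, p] * depth_fac[2 * (p - 1) + s]
      }
    }

    ## --- planted variability QTLs -------------------------------------
    qtl_peaks <- if (n_qtls > 0) sample.int(m, n_qtls) else integer(0)
    qtl_truth <- list()
    for (k in seq_along(qtl_peaks)) {
      j <- qtl_peaks[k]
      maf <- runif(1, 0.1, 0.5)
      g <- rbinom(n_pairs, 2, maf)
      pos <- pmin(assets$genome_size %/% length(assets$sequences) - 1L,
                  pmax(0L, floor((peaks$start[j] + peaks$end[j]) / 2) +
                         sample(c(-1, 1), 1) * sample.int(1e5, 1)))
      boosted <- sample(1:2, n_pairs, replace = TRUE)
      t_shift <- pmin(0.8, qtl_beta * g)
      for (p in seq_len(n_pairs)) {
        if (t_shift[p] > 0) {
          col <- 2 * (p - 1) + boosted[p]
          mu[j, col] <- mu[j, col] * (1 + t_shift[p]) / (1 - t_shift[p])
        }
      }
      qtl_truth[[k]] <- list(snp_id = sprintf("snp_qtl%02d", k),
                             chrom = peaks$chrom[j], pos = pos,
                             peak_id = peaks$peak_id[j], beta = qtl_beta,
                             maf = maf, dosage = g)
    }

    ## --- planted mutations (accessibility effects on the carrier) -----
    tfbs_peak <- locate_in_peaks(tf$chrom, tf$start, peaks)
    tfbs_pick <- sample.int(nrow(tf), n_mutations, replace = TRUE)
    mut_pos <- tf$start[tfbs_pick] +
      vapply(tfbs_pick, function(i) sample.int(tf$end[i] - tf$start[i], 1), integer(1)) - 1L
    dup <- duplicated(paste(tf$chrom[tfbs_pick], mut_pos))
    while (any(dup)) {
      i <- which(dup)
      tfbs_pick[i] <- sample.int(nrow(tf), length(i), replace = TRUE)
      mut_pos[i] <- tf$start[tfbs_pick[i]] +
        vapply(tfbs_pick[i], function(k) sample.int(tf$end[k] - tf$start[k], 1), integer(1)) - 1L
      dup <- duplicated(paste(tf$chrom[tfbs_pick], mut_pos))
    }
    mut_pair <- sample(pair_id, n_mutations, replace = TRUE)
    mut_carrier <- sample(1:2, n_mutations, replace = TRUE)
    mut_effect <- sample(c("decrease", "increase"), n_mutations, TRUE, c(0.7, 0.3))
    for (i in seq_len(n_mutations)) {
      j <- tfbs_peak[tfbs_pick[i]]
      p <- match(mut_pair[i], pair_id)
      col <- 2 * (p - 1) + mut_carrier[i]
      mu[j, col] <- mu[j, col] * ifelse(mut_effect[i] == "decrease", 0.4, 2.2)
    }

    counts <- matrix(rnbinom(m * 2 * n_pairs, mu = mu, size = 1 / dispersion),
                     m, 2 * n_pairs, dimnames = dimnames(mu))

    ## --- allele count table -------------------------------------------
    getbase <- function(chrom, pos) substr(assets$sequences[chrom], pos + 1, pos + 1)
    other_base <- function(b) vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))

    peak_positions <- function(n) {
      idx <- sample.int(m, n, replace = TRUE)
      pos <- peaks$start[idx] +
        vapply(idx, function(i) sample.int(peaks$end[i] - peaks$start[i], 1), integer(1)) - 1L
      data.frame(chrom = peaks$chrom[idx], pos = pos, stringsAsFactors = FALSE)
    }
    mut_df <- data.frame(chrom = tf$chrom[tfbs_pick], pos = mut_pos, stringsAsFactors = FALSE)
    used <- paste(mut_df$chrom, mut_df$pos)
    poly_df <- peak_positions(n_polymorphisms + n_null_positions + 50)
    poly_df <- poly_df[!paste(poly_df$chrom, poly_df$pos) %in% used, ]
    poly_df <- poly_df[!duplicated(paste(poly_df$chrom, poly_df$pos)), ]
    null_df <- poly_df[seq_len(min(n_null_positions, max(0, nrow(poly_df) - n_polymorphisms))) + n_polymorphisms, ]
    poly_df <- poly_df[seq_len(n_polymorphisms), ]

    pos_all <- rbind(
      cbind(mut_df, kind = rep("mutation", nrow(mut_df))),
      cbind(poly_df, kind = rep("polymorphism", nrow(poly_df))),
      cbind(null_df, kind = rep("null", nrow(null_df)))
    )
    pos_all$ref <- getbase(pos_all$chrom, pos_all$pos)
    pos_all$alt <- other_base(pos_all$ref)

    paf <- runif(n_polymorphisms, 0.1, 0.4)
    poly_dosage <- matrix(rbinom(n_polymorphisms * n_pairs, 2, rep(paf, n_pairs)),
                          n_polymorphisms, n_pairs)

    n_pos <- nrow(pos_all)
    n_smp <- 2 * n_pairs
    vaf <- matrix(0, n_pos, n_smp)
    for (i in seq_len(n_mutations)) {
      p <- match(mut_pair[i], pair_id)
      vaf[i, 2 * (p - 1) + mut_carrier[i]] <- mutation_vaf
    }
    for (i in seq_len(n_polymorphisms)) {
      vaf[n_mutations + i, ] <- rep(poly_dosage[i, ] / 2, each = 2)
    }

    tot <- matrix(rpois(n_pos * n_smp, allele_depth), n_pos, n_smp)
    p_alt <- vaf + (1 - 2 * vaf) * error_rate
    altn <- matrix(rbinom(n_pos * n_smp, tot, p_alt), n_pos, n_smp)
    refn <- tot - altn
    fwd_alt <- matrix(rbinom(n_pos * n_smp, altn, 0.5), n_pos, n_smp)
    fwd_ref <- matrix(rbinom(n_pos * n_smp, refn, 0.5), n_pos, n_smp)
    rev_alt <- altn - fwd_alt
    rev_ref <- refn - fwd_ref
    hq_fwd <- matrix(rbinom(n_pos * n_smp, fwd_alt + fwd_ref, hq_rate), n_pos, n_smp)
    hq_rev <- matrix(rbinom(n_pos * n_smp, rev_alt + rev_ref, hq_rate), n_pos, n_smp)

    alleles <- data.frame(
      chrom = rep(pos_all$chrom, n_smp),
      pos = rep(pos_all$pos, n_smp),
      ref = rep(pos_all$ref, n_smp),
      alt = rep(pos_all$alt, n_smp),
      sample = rep(samples, each = n_pos),
      fwd_ref = as.vector(fwd_ref), rev_ref = as.vector(rev_ref),
      fwd_alt = as.vector(fwd_alt), rev_alt = as.vector(rev_alt),
      hq_fwd = as.vector(hq_fwd), hq_rev = as.vector(hq_rev),
      stringsAsFactors = FALSE
    )
    alleles <- alleles[order(alleles$chrom, alleles$pos, alleles$sample), ]
    rownames(alleles) <- NULL

    ## --- genotype matrix (QTL + background SNPs) ----------------------
    contigs <- names(assets$sequences)
    clen <- nchar(assets$sequences)
    bg_chrom <- sample(contigs, n_background_snps, replace = TRUE)
    bg_pos <- floor(runif(n_background_snps, 0, clen[bg_chrom]))
    bg_maf <- runif(n_background_snps, 0.05, 0.5)
    bg_dos <- matrix(rbinom(n_background_snps * n_pairs, 2, rep(bg_maf, n_pairs)),
                     n_background_snps, n_pairs)
    snp_positions <- data.frame(
      snp_id = c(vapply(qtl_truth, `[[`, character(1), "snp_id"),
                 sprintf("snp_bg%03d", seq_len(n_background_snps))),
      chrom = c(vapply(qtl_truth, `[[`, character(1), "chrom"), bg_chrom),
      pos = c(vapply(qtl_truth, function(q) as.integer(q$pos), integer(1)), as.integer(bg_pos)),
      stringsAsFactors = FALSE
    )
    genotypes <- rbind(
      if (length(qtl_truth)) do.call(rbind, lapply(qtl_truth, `[[`, "dosage")) else NULL,
      bg_dos
    )
    rownames(genotypes) <- snp_positions$snp_id
    genotypes <- t(genotypes)
    rownames(genotypes) <- pair_id

    truth <- list(
      mutations = data.frame(
        chrom = mut_df$chrom, pos = mut_df$pos,
        ref = pos_all$ref[seq_len(n_mutations)], alt = pos_all$alt[seq_len(n_mutations)],
        pair_id = mut_pair, carrier = mut_carrier, effect = mut_effect,
        peak_id = peaks$peak_id[tfbs_peak[tfbs_pick]], stringsAsFactors = FALSE),
      polymorphisms = data.frame(
        chrom = poly_df$chrom, pos = poly_df$pos,
        ref = pos_all$ref[n_mutations + seq_len(n_polymorphisms)],
        alt = pos_all$alt[n_mutations + seq_len(n_polymorphisms)],
        pop_af = paf,
        pooled_dosage_af = rowMeans(poly_dosage) / 2, stringsAsFactors = FALSE),
      qtls = if (length(qtl_truth)) data.frame(
        snp_id = vapply(qtl_truth, `[[`, character(1), "snp_id"),
        chrom = vapply(qtl_truth, `[[`, character(1), "chrom"),
        pos = vapply(qtl_truth, function(q) as.integer(q$pos), integer(1)),
        peak_id = vapply(qtl_truth, `[[`, character(1), "peak_id"),
        beta = vapply(qtl_truth, `[[`, numeric(1), "beta"),
        maf = vapply(qtl_truth, `[[`, numeric(1), "maf"), stringsAsFactors = FALSE)
      else data.frame()
    )

    structure(list(pairing = pairing, counts = counts, alleles = alleles,
                   genotypes = genotypes, snp_positions = snp_positions,
                   truth = truth),
              class = "twin_cohort_sim")
  })
}

#' @export
print.twin_cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic twin cohort: %d pairs, %d peaks, %d allele positions, %d SNPs\n",
              nrow(x$genotypes), nrow(x$counts),
              length(unique(paste(x$alleles$chrom, x$alleles$pos))),
              ncol(x$genotypes)))
  cat(sprintf("Planted truth: %d mutations, %d polymorphisms, %d QTLs\n",
              nrow(x$truth$mutations), nrow(x$truth$polymorphisms), nrow(x$truth$qtls)))
  invisible(x)
}

#' Generate expression coupled to promoter accessibility discordance
#'
#' Genes linked to a promoter meta-peak (TSS within 2 kb) receive a
#' within-pair log2 expression split proportional to the pair's normalized
#' accessibility discordance at that peak:
#' `|e1 - e2| = coupling_strength * D_norm` plus Gaussian noise, with random
#' direction. Unlinked genes have no coupling.
#'
#' @param cohort a `twin_cohort_sim`.
#' @param assets the `genome_assets` the cohort was generated from.
#' @param coupling_strength slope of |delta log2 expression| on discordance
#'   (default 1.5).
#' @param noise_sd per-sample log2 noise (default 0.25).
#' @param seed RNG seed.
#' @return list: `expression` (gene x sample log2 matrix), `truth`
#'   (data.frame `gene_id`, `peak_id`, `coupling`).
#' @export
generate_expression <- function(cohort, assets, coupling_strength = 1.5,
                                noise_sd = 0.25, seed = 1) {
  links <- link_genes_to_peaks(assets$tss, assets$peaks, window = 2000)
  A <- quantile_normalize(normalize_accessibility(cohort$counts, assets$peaks,
                                                  assets$genome_size))
  disc <- pair_discordance(A, cohort$pairing)
  dmat <- matrix(0, nrow(assets$peaks), length(pair_ids(cohort$pairing)),
                 dimnames = list(assets$peaks$peak_id, pair_ids(cohort$pairing)))
  dmat[cbind(match(disc$peak_id, rownames(dmat)), match(disc$pair_id, colnames(dmat)))] <-
    ifelse(is.na(disc$d_norm), 0, disc$d_norm)

  with_rng(seed, {
    genes <- assets$tss$gene_id
    n_g <- length(genes)
    pid <- pair_ids(cohort$pairing)
    n_p <- length(pid)
    s1 <- sibling_samples(cohort$pairing, 1L)
    s2 <- sibling_samples(cohort$pairing, 2L)
    base <- rnorm(n_g, 8, 1)
    pair_fx <- matrix(rnorm(n_g * n_p, 0, 0.1), n_g, n_p)
    delta <- matrix(0, n_g, n_p)
    li <- match(genes, links$gene_id)
    linked <- !is.na(li)
    delta[linked, ] <- coupling_strength * dmat[links$peak_id[li[linked]], , drop = FALSE]
    sgn <- matrix(sample(c(-1, 1), n_g * n_p, TRUE), n_g, n_p)
    e1 <- base + pair_fx + sgn * delta / 2 + matrix(rnorm(n_g * n_p, 0, noise_sd), n_g, n_p)
    e2 <- base + pair_fx - sgn * delta / 2 + matrix(rnorm(n_g * n_p, 0, noise_sd), n_g, n_p)
    expr <- matrix(0, n_g, 2 * n_p, dimnames = list(genes, c(s1, s2)))
    expr[, s1] <- e1
    expr[, s2] <- e2
    expr <- expr[, cohort$pairing$sample_id]
    truth <- data.frame(gene_id = genes[linked],
                        peak_id = links$peak_id[li[linked]],
                        coupling = coupling_strength, stringsAsFactors = FALSE)
    list(expression = expr, truth = truth)
  })
}

#' Generate cell-type methylation profiles for TFBS CpGs
#'
#' For each CpG inside a TFBS, methylation levels in four cell types
#' (lymphocyte, ESC, HPC, neutrophil). A `regulated_fraction` of CpGs is
#' flagged as differentiation-regulated: their lymphocyte level differs from
#' ESC by `delta` on average (HPC intermediate at 0.6 delta, neutrophil — a
#' differentiated lineage like the lymphocyte — at 0.25 delta), with gain and
#' loss directions equally likely. Unregulated CpGs share one level across
#' cell types up to noise. All values are clipped to \[0, 1\], which shrinks
#' large deltas.
#'
#' @param assets a `genome_assets`.
#' @param regulated_fraction fraction of CpGs flagged regulated (default 0.3).
#' @param delta target |lymphocyte - ESC| methylation difference in \[0, 1\]
#'   (default 0.5).
#' @param seed RNG seed.
#' @return list: `methylation` (data.frame `chrom`, `pos`, `tfbs_id`,
#'   `lymphocyte`, `ESC`, `HPC`, `neutrophil`), `truth` (same keys +
#'   `regulated` flag).
#' @export
generate_methylation <- function(assets, regulated_fraction = 0.3, delta = 0.5, seed = 1) {
  if (delta < 0 || delta > 1) stopf("delta must be in [0, 1]")
  if (regulated_fraction < 0 || regulated_fraction > 1) stopf("regulated_fraction must be in [0, 1]")
  cp <- assets$cpg_positions
  hp <- overlap_pairs(data.frame(chrom = cp$chrom, start = cp$pos, end = cp$pos + 2), assets$tfbs)
  cp <- cp[hp$query, , drop = FALSE]
  cp$tfbs_id <- assets$tfbs$tfbs_id[hp$subject]
  with_rng(seed, {
    n <- nrow(cp)
    reg <- runif(n) < regulated_fraction
    gain <- runif(n) < 0.5   # lymphocyte more methylated than ESC, or less
    anchor <- ifelse(gain, rbeta(n, 8, 2), rbeta(n, 2, 8))
    dirn <- ifelse(gain, -1, 1)
    noise <- function() rnorm(n, 0, 0.02)
    lym <- ESC <- HPC <- neu <- numeric(n)
    # unregulated: one shared level
    m0 <- rbeta(n, 2, 2)
    lym <- clip01(ifelse(reg, anchor, m0) + noise())
    ESC <- clip01(ifelse(reg, anchor + dirn * delta, m0) + noise())
    HPC <- clip01(ifelse(reg, anchor + dirn * 0.6 * delta, m0) + noise())
    neu <- clip01(ifelse(reg, anchor + dirn * 0.25 * delta, m0) + noise())
    meth <- data.frame(chrom = cp$chrom, pos = cp$pos, tfbs_id = cp$tfbs_id,
                       lymphocyte = lym, ESC = ESC, HPC = HPC, neutrophil = neu,
                       stringsAsFactors = FALSE)
    truth <- data.frame(chrom = cp$chrom, pos = cp$pos, regulated = reg,
                        stringsAsFactors = FALSE)
    if (regulated_fraction == 0) truth$regulated <- FALSE
    list(methylation = meth, truth = truth)
  })
}
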