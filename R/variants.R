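#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided p: the sum of hypergeometric probabilities,
#' over all tables with the observed margins, of tables no more probable than
#' the observed one. For tables where the integer enumeration weights stay
#' below 2^53 the comparison is exact integer arithmetic; larger tables fall
#' back to log-space comparison with relative tolerance 1e-7 (the usual
#' convention). Degenerate margins give p = 1.
#'
#' @param table 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts `[[a, b], [c, d]]`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.vector(as.matrix(table))
  if (length(x) != 4) stopf("need a 2x2 table")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stopf("table entries must be finite non-negative integers")
  }
  a <- x[1]; c <- x[2]; b <- x[3]; d <- x[4]  # column-major: [[a,b],[c,d]]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  aa <- lo:hi
  w <- choose(r1, aa) * choose(r2, c1 - aa)
  if (max(w) < 2^53) {
    sel <- w <= w[aa == a]
    p <- sum(w[sel]) / choose(n, c1)
  } else {
    lw <- lchoose(r1, aa) + lchoose(r2, c1 - aa)
    sel <- lw <= lw[aa == a] + 1e-7
    p <- sum(exp(lw[sel] - lchoose(n, c1)))
  }
  min(1, p)
}

#' Call somatic mutations from paired allele counts
#'
#' A somatic mutation is a within-pair single-nucleotide difference. At every
#' position shared by both siblings of a pair, the sibling-by-allele read
#' count table `[[ref1, alt1], [ref2, alt2]]` is tested with
#' [fisher_exact_two_sided()]. A call is emitted when
#' `p < p_threshold`, each sibling has at least `min_hq_per_strand`
#' high-quality reads on each strand, and the carrier sibling (the one with
#' the higher alt-read fraction) shows the variant allele on both strands
#' with at least `min_alt_per_strand` reads each (the high-confidence proxy).
#'
#' @param alleles allele count table: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `sample`, `fwd_ref`, `rev_ref`, `fwd_alt`, `rev_alt`, `hq_fwd`, `hq_rev`.
#' @param pairing a [twin_cohort()].
#' @param p_threshold Fisher p cutoff (default 1e-3).
#' @param min_hq_per_strand minimum high-quality reads per strand per sibling
#'   (default 10).
#' @param min_alt_per_strand minimum variant reads per strand in the carrier
#'   (default 2).
#'
#' @return A data.frame of calls: `chrom`, `pos`, `ref`, `alt`,
#'   `class = "somatic_mutation"`, `pair_id`, `carrier` (sibling 1/2),
#'   `p_value`, plus the carrier/non-carrier read counts.
#' @export
call_somatic_mutations <- function(alleles, pairing, p_threshold = 1e-3,
                                   min_hq_per_strand = 10, min_alt_per_strand = 2) {
  al <- merge(alleles, as.data.frame(pairing), by.x = "sample", by.y = "sample_id")
  a1 <- al[al$sibling == 1L, ]
  a2 <- al[al$sibling == 2L, ]
  key <- function(d) paste(d$chrom, d$pos, d$pair_id, sep = ":")
  k1 <- key(a1); k2 <- key(a2)
  common <- intersect(k1, k2)
  dropped <- (length(k1) - length(common)) + (length(k2) - length(common))
  if (dropped > 0) message(dropped, " sibling-absent position records skipped")
  a1 <- a1[match(common, k1), ]
  a2 <- a2[match(common, k2), ]

  ref1 <- a1$fwd_ref + a1$rev_ref; alt1 <- a1$fwd_alt + a1$rev_alt
  ref2 <- a2$fwd_ref + a2$rev_ref; alt2 <- a2$fwd_alt + a2$rev_alt
  hq_ok <- a1$hq_fwd >= min_hq_per_strand & a1$hq_rev >= min_hq_per_strand &
    a2$hq_fwd >= min_hq_per_strand & a2$hq_rev >= min_hq_per_strand
  f1 <- ifelse(ref1 + alt1 > 0, alt1 / (ref1 + alt1), 0)
  f2 <- ifelse(ref2 + alt2 > 0, alt2 / (ref2 + alt2), 0)
  carrier1 <- f1 >= f2
  c_fwd_alt <- ifelse(carrier1, a1$fwd_alt, a2$fwd_alt)
  c_rev_alt <- ifelse(carrier1, a1$rev_alt, a2$rev_alt)
  strand_ok <- c_fwd_alt >= min_alt_per_strand & c_rev_alt >= min_alt_per_strand
  cand <- which(hq_ok & strand_ok & (alt1 + alt2) > 0)

  p <- rep(NA_real_, length(common))
  for (i in cand) {
    p[i] <- fisher_exact_two_sided(matrix(c(ref1[i], ref2[i], alt1[i], alt2[i]), 2))
  }
  hit <- cand[p[cand] < p_threshold]
  out <- data.frame(
    chrom = a1$chrom[hit], pos = a1$pos[hit],
    ref = a1$ref[hit], alt = a1$alt[hit],
    class = rep("somatic_mutation", length(hit)),
    pair_id = a1$pair_id[hit],
    carrier = ifelse(carrier1[hit], 1L, 2L),
    p_value = p[hit],
    carrier_ref = ifelse(carrier1[hit], ref1[hit], ref2[hit]),
    carrier_alt = ifelse(carrier1[hit], alt1[hit], alt2[hit]),
    other_ref = ifelse(carrier1[hit], ref2[hit], ref1[hit]),
    other_alt = ifelse(carrier1[hit], alt2[hit], alt1[hit]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos, out$pair_id), ]
  rownames(out) <- NULL
  out
}

#' Call polymorphisms from pooled allele counts
#'
#' A polymorphism is a variant shared across the cohort rather than differing
#' within a pair: the position must be covered by at least one read in every
#' sample, must not be a somatic-mutation call in any pair, and the pooled
#' minor-allele read fraction across all samples must reach `maf_threshold`.
#' Candidates where, in every carrier sample (alt reads > 0), more than
#' `strand_frac` of the variant-supporting reads come from a single strand
#' are removed as alignment artifacts. Only positions on `contigs` (the
#' autosome allow-list) are considered when given.
#'
#' @inheritParams call_somatic_mutations
#' @param somatic_calls optional output of [call_somatic_mutations()]; their
#'   positions are excluded.
#' @param maf_threshold pooled minor-allele frequency cutoff (default 0.01).
#' @param strand_frac one-strand fraction above which a carrier is
#'   strand-biased (default 0.90).
#' @param contigs optional character vector of allowed contigs.
#'
#' @return data.frame of calls: `chrom`, `pos`, `ref`, `alt`,
#'   `class = "polymorphism"`, `pooled_maf`, `pooled_alt_frac`.
#' @export
call_polymorphisms <- function(alleles, pairing, somatic_calls = NULL,
                               maf_threshold = 0.01, strand_frac = 0.90,
                               contigs = NULL) {
  al <- alleles
  if (!is.null(contigs)) al <- al[al$chrom %in% contigs, ]
  n_samples <- nrow(pairing)
  al$total <- al$fwd_ref + al$rev_ref + al$fwd_alt + al$rev_alt
  al$alt_n <- al$fwd_alt + al$rev_alt
  k <- paste(al$chrom, al$pos, sep = ":")
  # covered in all samples: require a record with >=1 read for every sample
  per_pos_samples <- tapply(al$sample[al$total >= 1], k[al$total >= 1],
                            function(s) length(unique(s)))
  covered <- names(per_pos_samples)[per_pos_samples == n_samples]
  al <- al[k %in% covered, ]
  k <- paste(al$chrom, al$pos, sep = ":")
  if (!is.null(somatic_calls) && nrow(somatic_calls)) {
    k_som <- paste(somatic_calls$chrom, somatic_calls$pos, sep = ":")
    keep <- !(k %in% k_som)
    al <- al[keep, ]; k <- k[keep]
  }
  if (!nrow(al)) return(empty_poly_calls())

  alt_tot <- tapply(al$alt_n, k, sum)
  all_tot <- tapply(al$total, k, sum)
  f <- as.numeric(alt_tot / all_tot)
  maf <- pmin(f, 1 - f)
  pass <- names(alt_tot)[maf >= maf_threshold & f > 0]
  if (!length(pass)) return(empty_poly_calls())

  # strand filter: drop if every carrier sample is one-strand dominated
  biased <- vapply(pass, function(kk) {
    d <- al[k == kk & al$alt_n > 0, ]
    all(pmax(d$fwd_alt, d$rev_alt) / d$alt_n > strand_frac)
  }, logical(1))
  pass <- pass[!biased]
  idx <- match(pass, k)
  out <- data.frame(
    chrom = al$chrom[idx], pos = al$pos[idx],
    ref = al$ref[idx], alt = al$alt[idx],
    class = rep("polymorphism", length(idx)),
    pooled_alt_frac = f[match(pass, names(alt_tot))],
    pooled_maf = maf[match(pass, names(alt_tot))],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

empty_poly_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), class = character(), pooled_alt_frac = numeric(),
             pooled_maf = numeric(), stringsAsFactors = FALSE)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Strand-collapsed base-change class
#'
#' Maps a ref > alt substitution and its reverse complement onto one of the
#' six classes `C:G>T:A`, `C:G>A:T`, `C:G>G:C`, `A:T>G:C`, `A:T>C:G`,
#' `A:T>T:A` (the pyrimidine-from-C / purine-from-A strand is taken as
#' canonical).
#'
#' @param ref,alt single reference / alternate bases (vectorized).
#' @return character vector of class labels.
#' @export
base_change_class <- function(ref, alt) {
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    stopf("bases must be A/C/G/T")
  }
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  sprintf("%s:%s>%s:%s", r, comp_base(r), a, comp_base(a))
}

#' Type calls by base change, gated on reference homozygosity
#'
#' A change is only typed (its direction from the reference known) when one
#' configuration is reference-homozygous: for somatic mutations the
#' non-carrier sibling must show zero alt reads; for polymorphisms the pooled
#' alt-read fraction must not exceed 0.5 (the reference allele is the major
#' one). Other calls are kept with `base_change = NA` (unclassified).
#'
#' @param calls a call table from [call_somatic_mutations()] or
#'   [call_polymorphisms()].
#' @return `calls` with columns `base_change` and `change_eligible` added.
#' @export
classify_base_change <- function(calls) {
  if (!nrow(calls)) {
    calls$base_change <- character(0); calls$change_eligible <- logical(0)
    return(calls)
  }
  eligible <- if (all(calls$class == "somatic_mutation")) {
    calls$other_alt == 0
  } else if (all(calls$class == "polymorphism")) {
    calls$pooled_alt_frac <= 0.5
  } else {
    stopf("mixed call classes; classify mutations and polymorphisms separately")
  }
  calls$change_eligible <- eligible
  calls$base_change <- ifelse(eligible, base_change_class(calls$ref, calls$alt), NA_character_)
  calls
}

#' Peak context of mutation calls
#'
#' Annotates each call with the distance from the mutation to the center of
#' its host meta-peak, `|pos - floor((start + end) / 2)|`, and each peak with
#' its mutation density (#mutations / peak length). Calls outside all peaks
#' are flagged with missing context.
#'
#' @param calls call table with `chrom`, `pos`.
#' @param peaks meta-peak table.
#' @return list with `calls` (context columns added: `peak_id`,
#'   `dist_to_center`) and `peak_density` (`peak_id`, `n_mutations`,
#'   `mutations_per_bp`).
#' @export
annotate_mutation_peak_context <- function(calls, peaks) {
  pk <- locate_in_peaks(calls$chrom, calls$pos, peaks)
  if (any(is.na(pk))) message(sum(is.na(pk)), " call(s) outside all peaks; context missing")
  center <- floor((peaks$start + peaks$end) / 2)
  calls$peak_id <- ifelse(is.na(pk), NA_character_, peaks$peak_id[pk])
  calls$dist_to_center <- ifelse(is.na(pk), NA_real_, abs(calls$pos - center[pk]))
  tab <- table(factor(calls$peak_id, levels = peaks$peak_id))
  dens <- data.frame(
    peak_id = peaks$peak_id,
    n_mutations = as.integer(tab),
    mutations_per_bp = as.integer(tab) / (peaks$end - peaks$start),
    stringsAsFactors = FALSE
  )
  list(calls = calls, peak_density = dens[dens$n_mutations > 0, ])
}

#' Encode per-sample SNP dosages from allele read counts
#'
#' Genotype dosage (count of alt alleles, 0/1/2) called from the per-sample
#' alt-read fraction: below 0.25 -> 0, between 0.25 and 0.75 -> 1, above
#' 0.75 -> 2; samples with no reads get `NA`.
#'
#' @param alleles allele count table (see [call_somatic_mutations()]).
#' @param positions data.frame `chrom`, `pos` of the sites to encode.
#' @param samples sample ids defining the column order.
#' @return integer matrix, positions x samples, rownames `chrom:pos`.
#' @export
snp_dosage_from_alleles <- function(alleles, positions, samples) {
  keys <- paste(positions$chrom, positions$pos, sep = ":")
  ak <- paste(alleles$chrom, alleles$pos, sep = ":")
  out <- matrix(NA_integer_, nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, samples))
  sub <- alleles[ak %in% keys, ]
  tot <- sub$fwd_ref + sub$rev_ref + sub$fwd_alt + sub$rev_alt
  f <- ifelse(tot > 0, (sub$fwd_alt + sub$rev_alt) / tot, NA_real_)
  dos <- ifelse(is.na(f), NA_integer_, ifelse(f < 0.25, 0L, ifelse(f <= 0.75, 1L, 2L)))
  out[cbind(match(paste(sub$chrom, sub$pos, sep = ":"), keys), match(sub$sample, samples))] <- dos
  out
}

#' Associate SNP dosage with host-peak accessibility
#'
#' Ordinary least-squares regression of the (quantile-normalized)
#' accessibility of the peak containing each SNP on per-sample genotype
#' dosage, with BH step-up FDR over the tested SNPs.
#'
#' @param dosage SNP x sample dosage matrix (e.g. from
#'   [snp_dosage_from_alleles()]).
#' @param positions data.frame `chrom`, `pos` aligned with `dosage` rows.
#' @param mat accessibility matrix (peaks x samples; rownames = peak ids).
#' @param peaks meta-peak table locating the SNPs.
#' @param fdr significance cutoff on the adjusted q (default 0.05).
#' @return data.frame `snp`, `peak_id`, `n`, `slope`, `t`, `p`, `q`,
#'   `significant`; SNPs outside peaks or with constant dosage are skipped.
#' @export
associate_snp_accessibility <- function(dosage, positions, mat, peaks, fdr = 0.05) {
  pk <- locate_in_peaks(positions$chrom, positions$pos, peaks)
  res <- data.frame(snp = rownames(dosage), peak_id = peaks$peak_id[pk],
                    n = NA_integer_, slope = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    if (is.na(pk[i])) next
    y <- mat[res$peak_id[i], colnames(dosage)]
    g <- as.numeric(dosage[i, ])
    ok <- !is.na(g) & !is.na(y)
    if (sum(ok) < 3 || var(g[ok]) == 0) {
      if (sum(ok) >= 3) warnf("SNP %s has constant dosage; skipped", res$snp[i])
      next
    }
    fit <- ols_slope_test(g[ok], y[ok])
    res$n[i] <- sum(ok); res$slope[i] <- fit$slope; res$t[i] <- fit$t; res$p[i] <- fit$p
  }
  tested <- !is.na(res$p)
  res$q <- NA_real_
  res$q[tested] <- fdr_adjust(res$p[tested])
  res$significant <- !is.na(res$q) & res$q < fdr
  res
}

## closed-form simple linear regression slope t-test (validated against lm)
ols_slope_test <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  t <- if (se == 0) sign(b) * Inf else b / se
  p <- 2 * pt(-abs(t), df)
  list(slope = b, t = t, p = p, df = df)
}

#' Direction of a mutation's accessibility effect
#'
#' For each somatic-mutation call, compares the accessibility of the host
#' meta-peak between the carrier and the non-carrier sibling:
#' `"increase"` when the carrier is more accessible, `"decrease"` when less,
#' `"unclassified"` when the call has no host peak or the values tie.
#'
#' @param calls somatic-mutation call table.
#' @param mat accessibility matrix (peaks x samples).
#' @param peaks meta-peak table.
#' @param pairing a [twin_cohort()].
#' @return `calls` with a `direction` column added.
#' @export
mutation_direction <- function(calls, mat, peaks, pairing) {
  if (!nrow(calls)) { calls$direction <- character(0); return(calls) }
  pk <- locate_in_peaks(calls$chrom, calls$pos, peaks)
  dir <- rep("unclassified", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(pk[i])) next
    pr <- pairing[pairing$pair_id == calls$pair_id[i], ]
    sc <- pr$sample_id[pr$sibling == calls$carrier[i]]
    so <- pr$sample_id[pr$sibling != calls$carrier[i]]
    xc <- mat[peaks$peak_id[pk[i]], sc]
    xo <- mat[peaks$peak_id[pk[i]], so]
    if (xc > xo) dir[i] <- "increase" else if (xc < xo) dir[i] <- "decrease"
  }
  calls$direction <- dir
  calls
}
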