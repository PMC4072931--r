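# Shared fixture builders. Everything is generated in code at test time.

# one allele-table row per (position, sample)
allele_row <- function(chrom = "chr1", pos, ref = "C", alt = "A", sample,
                       fwd_ref, rev_ref, fwd_alt, rev_alt,
                       hq_fwd = fwd_ref + fwd_alt, hq_rev = rev_ref + rev_alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, sample = sample,
             fwd_ref = fwd_ref, rev_ref = rev_ref, fwd_alt = fwd_alt,
             rev_alt = rev_alt, hq_fwd = hq_fwd, hq_rev = hq_rev,
             stringsAsFactors = FALSE)
}

# a pair of siblings with given per-sibling (ref, alt) totals, strand-balanced
pair_alleles <- function(pos, ref1, alt1, ref2, alt2, pair = "p1",
                         ref = "C", alt = "A", hq = NULL) {
  half <- function(n) c(floor(n / 2), ceiling(n / 2))
  r1 <- half(ref1); a1 <- half(alt1); r2 <- half(ref2); a2 <- half(alt2)
  rows <- rbind(
    allele_row(pos = pos, ref = ref, alt = alt, sample = paste0(pair, "_1"),
               fwd_ref = r1[1], rev_ref = r1[2], fwd_alt = a1[1], rev_alt = a1[2]),
    allele_row(pos = pos, ref = ref, alt = alt, sample = paste0(pair, "_2"),
               fwd_ref = r2[1], rev_ref = r2[2], fwd_alt = a2[1], rev_alt = a2[2])
  )
  if (!is.null(hq)) rows$hq_fwd <- rows$hq_rev <- hq
  rows
}

make_pairing <- function(n_pairs) {
  pid <- sprintf("p%d", seq_len(n_pairs))
  twin_cohort(as.vector(rbind(paste0(pid, "_1"), paste0(pid, "_2"))),
              rep(pid, each = 2), rep(1:2, n_pairs))
}

# exhaustive per-bp interval union oracle (0-based half-open)
brute_union <- function(sets, max_bp = 1e4) {
  all <- do.call(rbind, sets)
  out <- list()
  for (ch in unique(all$chrom)) {
    cov <- logical(max_bp)
    sub <- all[all$chrom == ch, ]
    for (i in seq_len(nrow(sub))) cov[(sub$start[i] + 1):sub$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exhaustive dinucleotide window-count oracle over a region set
brute_dinuc_counts <- function(seqs, regions = NULL) {
  classes <- dinuc_classes()
  counts <- setNames(numeric(length(classes)), classes)
  if (is.null(regions)) {
    regions <- data.frame(chrom = names(seqs), start = 0, end = nchar(seqs))
  }
  pal <- c("AT", "CG", "GC", "TA")
  for (i in seq_len(nrow(regions))) {
    s <- seqs[[regions$chrom[i]]]
    if (regions$end[i] - regions$start[i] < 2) next
    for (p in (regions$start[i] + 1):(regions$end[i] - 1)) {
      d <- substr(s, p, p + 1)
      cl <- collapse_dinucleotide(d)
      counts[cl] <- counts[cl] + if (d %in% pal) 2 else 1
    }
  }
  counts
}

revcomp_seq <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# minimum-likelihood two-sided Fisher p by direct dhyper enumeration
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  aa <- max(0, c1 - r2):min(r1, c1)
  dh <- dhyper(aa, c1, n - c1, r1)
  min(1, sum(dh[dh <= dh[aa == a] * (1 + 1e-7)]))
}
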