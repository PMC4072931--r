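#' Select high-variance discordance loci
#'
#' Within-pair chromatin differences are near zero at most loci, so QTL
#' mapping is restricted to the meta-peaks with the largest between-pair
#' variance in normalized discordance (the top 1% by default). Ties at the
#' selection boundary are broken by peak order (stable).
#'
#' @param disc a `discordance_table` from [pair_discordance()].
#' @param fraction fraction of peaks to keep (default 0.01).
#' @return character vector of selected `peak_id`s,
#'   `ceiling(fraction * n_peaks)` of them (at least one, with a warning when
#'   fewer peaks than `1/fraction` exist).
#' @export
select_top_variance_loci <- function(disc, fraction = 0.01) {
  if (!(fraction > 0 && fraction <= 1)) stopf("fraction must be in (0, 1]")
  pk <- unique(disc$peak_id)
  v <- vapply(split(disc$d_norm, factor(disc$peak_id, levels = pk)),
              function(y) var(y, na.rm = TRUE), numeric(1))
  m <- length(pk)
  if (m < 1 / fraction) warnf("only %d peaks for top fraction %g; returning 1 peak", m, fraction)
  k <- max(1L, ceiling(fraction * m))
  ord <- order(-v, seq_along(v))
  pk[ord[seq_len(k)]]
}

#' Map variability QTLs
#'
#' Associates genotype dosages shared by each twin pair with the pair's
#' normalized chromatin discordance `y = |X1 - X2| / (X1 + X2)` at the
#' selected peaks, by simple linear regression of y on dosage across pairs
#' for every (SNP, peak) combination closer than `cis_window`. SNPs are
#' filtered at minor allele frequency `maf_min`; q-values are BH step-up over
#' all tested cis combinations.
#'
#' @param disc a `discordance_table` restricted (or not) to the peaks of
#'   interest; use [select_top_variance_loci()] for the variance screen.
#' @param genotypes pair x SNP dosage matrix (rownames = pair ids, colnames =
#'   SNP ids; dosage 0/1/2, identical within a pair by MZ design).
#' @param snp_positions data.frame `snp_id`, `chrom`, `pos` (0-based).
#' @param peaks meta-peak table (for SNP-to-peak distances).
#' @param peak_ids peaks to test (default: all in `disc`).
#' @param cis_window maximum SNP-to-peak distance in bp (default 1e6,
#'   exclusive); distance is the gap between the SNP position and the peak
#'   interval, 0 inside.
#' @param fdr q-value significance cutoff (default 0.01).
#' @param maf_min minimum minor allele frequency among pairs (default 0.01).
#' @return data.frame `snp_id`, `peak_id`, `distance`, `n`, `slope`, `t`,
#'   `p`, `q`, `cis`, `significant`, one row per tested cis combination,
#'   ordered by (peak, snp).
#' @export
map_variability_qtl <- function(disc, genotypes, snp_positions, peaks,
                                peak_ids = NULL, cis_window = 1e6,
                                fdr = 0.01, maf_min = 0.01) {
  if (is.null(peak_ids)) peak_ids <- unique(disc$peak_id)
  peak_ids <- sort(peak_ids)
  snp_positions <- snp_positions[order(snp_positions$snp_id), , drop = FALSE]
  genotypes <- genotypes[sort(rownames(genotypes)), , drop = FALSE]

  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_snp <- !is.na(maf) & maf >= maf_min
  snp_positions <- snp_positions[snp_positions$snp_id %in% colnames(genotypes)[keep_snp], , drop = FALSE]

  pinfo <- peaks[match(peak_ids, peaks$peak_id), ]
  res <- vector("list", length(peak_ids))
  for (j in seq_along(peak_ids)) {
    pid <- peak_ids[j]
    same <- snp_positions$chrom == pinfo$chrom[j]
    gap <- pmax(0, pmax(pinfo$start[j] - snp_positions$pos,
                        snp_positions$pos - (pinfo$end[j] - 1L)))
    cis <- same & gap < cis_window
    if (!any(cis)) next
    d <- disc[disc$peak_id == pid, ]
    y <- setNames(d$d_norm, d$pair_id)[rownames(genotypes)]
    rows <- lapply(which(cis), function(s) {
      g <- genotypes[, snp_positions$snp_id[s]]
      ok <- !is.na(g) & !is.na(y)
      if (sum(ok) < 3 || var(g[ok]) == 0) return(NULL)
      fit <- ols_slope_test(g[ok], y[ok])
      data.frame(snp_id = snp_positions$snp_id[s], peak_id = pid,
                 distance = gap[s], n = sum(ok), slope = fit$slope,
                 t = fit$t, p = fit$p, stringsAsFactors = FALSE)
    })
    res[[j]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(snp_id = character(), peak_id = character(), distance = numeric(),
                      n = integer(), slope = numeric(), t = numeric(), p = numeric(),
                      q = numeric(), cis = logical(), significant = logical()))
  }
  out <- out[order(out$peak_id, out$snp_id), ]
  out$q <- fdr_adjust(out$p)
  out$cis <- TRUE
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Step-up false discovery rate adjustment
#'
#' Benjamini-Hochberg step-up q-values via [stats::p.adjust()], with input
#' validation. Monotone and order-preserving.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @return q-values in \[0, 1\], same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must be in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
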