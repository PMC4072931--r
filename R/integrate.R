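#' Within-pair differential expression
#'
#' Absolute log2 expression difference between twin siblings, per gene and
#' pair. Missing values propagate: a gene missing in either sibling is `NA`
#' for that pair.
#'
#' @param expr gene x sample matrix of log2 intensities (columns named by
#'   sample); normalize with [quantile_normalize()] first if needed.
#' @param pairing a [twin_cohort()].
#' @return gene x pair matrix of `|log2 e1 - log2 e2|`.
#' @export
within_pair_expression_diff <- function(expr, pairing) {
  miss <- setdiff(pairing$sample_id, colnames(expr))
  if (length(miss)) {
    bad_pairs <- unique(pairing$pair_id[pairing$sample_id %in% miss])
    warnf("pair(s) with missing sample columns skipped: %s", paste(bad_pairs, collapse = ", "))
    pairing <- pairing[!pairing$pair_id %in% bad_pairs, ]
  }
  s1 <- sibling_samples(pairing, 1L)
  s2 <- sibling_samples(pairing, 2L)
  out <- abs(expr[, s1, drop = FALSE] - expr[, s2, drop = FALSE])
  colnames(out) <- pair_ids(pairing)
  out
}

#' Link genes to their promoter meta-peak
#'
#' Each gene is linked to the nearest meta-peak whose interval lies within
#' `window` bp of the transcription start site (distance 0 when the TSS is
#' inside the peak); equidistant candidates resolve to the lower-coordinate
#' peak. Genes with no peak in the window are left unlinked.
#'
#' @param tss data.frame `gene_id`, `chrom`, `pos` (0-based TSS), `strand`.
#' @param peaks meta-peak table.
#' @param window promoter window in bp (default 2000, inclusive).
#' @return data.frame `gene_id`, `peak_id`, `distance` — linked genes only.
#' @export
link_genes_to_peaks <- function(tss, peaks, window = 2000) {
  res <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    same <- peaks$chrom == tss$chrom[i]
    if (!any(same)) next
    p <- peaks[same, ]
    gap <- pmax(0, pmax(p$start - tss$pos[i], tss$pos[i] - (p$end - 1L)))
    ok <- gap <= window
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[order(gap[cand], p$start[cand])][1]
    res[[i]] <- data.frame(gene_id = tss$gene_id[i], peak_id = p$peak_id[best],
                           distance = gap[best], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(), peak_id = character(),
                                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation test of the discordance-expression rank coupling
#'
#' Genes (or gene-pair observations) are binned into low/medium/high
#' tertiles of chromatin discordance; the statistic is the Spearman rank
#' correlation between the tertile index (1/2/3) and differential
#' expression. The null is built by permuting differential expression across
#' observations; the empirical p is `(b + 1) / (n_perm + 1)` with `b` the
#' number of permutations whose `|statistic|` reaches the observed one.
#' Because the statistic uses ranks it is invariant to monotone transforms
#' of the expression differences.
#'
#' @param discordance numeric per-observation chromatin discordance.
#' @param diff_expr numeric per-observation differential expression, same
#'   length.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return list `statistic` (observed rank correlation), `p`, `n_perm`,
#'   `tertile` (the bin index used).
#' @export
tertile_permutation_test <- function(discordance, diff_expr, n_perm = 10000, seed = NULL) {
  ok <- !is.na(discordance) & !is.na(diff_expr)
  discordance <- discordance[ok]; diff_expr <- diff_expr[ok]
  n <- length(discordance)
  if (n < 3) stopf("need at least 3 observations")
  if (n < 30) warnf("fewer than 30 observations; permutation p will be coarse")
  if (var(discordance) == 0) stopf("discordance is constant; tertiles undefined")
  r <- rank(discordance, ties.method = "first")
  tert <- as.integer(cut(r, breaks = quantile(r, c(0, 1/3, 2/3, 1)),
                         include.lowest = TRUE, labels = FALSE))
  stat <- function(de) cor(tert, rank(de))
  obs <- stat(diff_expr)
  run <- function() {
    b <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(stat(sample(diff_expr))) >= abs(obs) - 1e-12) b <- b + 1L
    }
    b
  }
  b <- if (is.null(seed)) run() else with_rng(seed, run())
  list(statistic = obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm, tertile = tert)
}

#' Differential CpG methylation by substitution status
#'
#' For each CpG and each non-reference cell type, the absolute methylation
#' difference from the reference cell type (lymphocyte) is computed; the
#' distributions are then compared between non-substituted CpGs and mutated
#' or polymorphic CpGs with two-sided rank-sum tests. Optionally, CpGs are
#' first averaged within their TFBS (`tfbs_id` column) before comparison.
#'
#' @param meth data.frame with columns `pos`, one column per cell type
#'   (levels in \[0, 1\]), a `status` column in
#'   `{"non_substituted", "mutated", "polymorphic"}`, and optionally
#'   `tfbs_id`.
#' @param reference_cell reference cell type column (default "lymphocyte").
#' @param cell_types comparison cell types (default ESC, HPC, neutrophil).
#' @param by_tfbs average deltas per TFBS before testing (default FALSE).
#' @return list `summary` (per status x cell type: n, mean and median delta)
#'   and `tests` (per cell type: rank-sum p of each substituted status vs
#'   non-substituted).
#' @export
cpg_differential_methylation_compare <- function(meth, reference_cell = "lymphocyte",
                                                 cell_types = c("ESC", "HPC", "neutrophil"),
                                                 by_tfbs = FALSE) {
  if (!reference_cell %in% names(meth)) stopf("missing reference cell column '%s'", reference_cell)
  summ <- list(); tests <- list()
  for (ct in cell_types) {
    if (!ct %in% names(meth)) stopf("missing cell type column '%s'", ct)
    delta <- abs(meth[[reference_cell]] - meth[[ct]])
    status <- meth$status
    if (by_tfbs) {
      if (is.null(meth$tfbs_id)) stopf("by_tfbs = TRUE needs a tfbs_id column")
      keep <- !is.na(meth$tfbs_id)
      agg <- aggregate(list(delta = delta[keep]),
                       list(tfbs = meth$tfbs_id[keep], status = meth$status[keep]),
                       mean)
      delta <- agg$delta
      status <- agg$status
    }
    for (st in unique(status)) {
      summ[[paste(ct, st)]] <- data.frame(
        cell_type = ct, status = st, n = sum(status == st),
        mean_delta = mean(delta[status == st], na.rm = TRUE),
        median_delta = median(delta[status == st], na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
    ref <- delta[status == "non_substituted"]
    for (st in c("mutated", "polymorphic")) {
      g <- delta[status == st]
      if (!length(g) || !length(ref)) {
        warnf("empty group '%s' for %s; comparison skipped", st, ct)
        next
      }
      tests[[paste(ct, st)]] <- data.frame(
        cell_type = ct, status = st,
        p = wilcox.test(g, ref, exact = FALSE)$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       tests = if (length(tests)) do.call(rbind, c(tests, list(make.row.names = FALSE))) else NULL)
}
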