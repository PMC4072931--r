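#' Merge per-sample peak sets into meta-peaks
#'
#' Open-chromatin peak calls from all samples are unioned into a single set of
#' disjoint "meta-peaks" that serves as the common quantification frame.
#' Touching (book-ended) intervals are merged.
#'
#' @param peak_sets a single interval data.frame or a list of them
#'   (`chrom`, `start`, `end`; 0-based half-open).
#'
#' @return A data.frame of disjoint sorted meta-peaks with columns `peak_id`,
#'   `chrom`, `start`, `end`, `length`.
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  for (p in peak_sets) validate_intervals(p, "peak")
  all <- do.call(rbind, lapply(peak_sets, function(p) p[, c("chrom", "start", "end")]))
  if (!nrow(all)) stopf("no peaks to merge")
  red <- GenomicRanges::reduce(as_granges0(all))  # merges overlaps and adjacency
  red <- GenomicRanges::sort(red)
  out <- as_bed0(red)
  out$length <- out$end - out$start
  out <- cbind(peak_id = sprintf("peak_%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalize read counts to chromatin accessibility
#'
#' Accessibility of meta-peak j in sample i is the tag enrichment relative to
#' genome background: `(c[j,i] / L_j) / (R_i / G)`, where `c` is the read
#' count, `L_j` the meta-peak length, `R_i` the sample's total read count over
#' all meta-peaks (column sum) and `G` the genome size. The metric is exactly
#' invariant to rescaling a sample's sequencing depth.
#'
#' @param counts integer matrix, meta-peaks x samples; rows must align with
#'   `peaks`.
#' @param peaks meta-peak table from [merge_peaks()].
#' @param genome_size genome length G in bp.
#'
#' @return A numeric matrix of class `accessibility_matrix` (peaks x samples)
#'   with attributes `sample_totals` (R) and `genome_size` (G).
#' @export
normalize_accessibility <- function(counts, peaks, genome_size) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(peaks)) stopf("counts rows (%d) != peaks (%d)", nrow(counts), nrow(peaks))
  if (any(counts < 0) || any(!is.finite(counts))) stopf("counts must be finite and non-negative")
  R <- colSums(counts)
  if (any(R == 0)) stopf("sample(s) with zero total reads: %s",
                         paste(colnames(counts)[R == 0], collapse = ", "))
  L <- peaks$end - peaks$start
  A <- (counts / L) / rep(R / genome_size, each = nrow(counts))
  rownames(A) <- peaks$peak_id
  structure(A, sample_totals = R, genome_size = genome_size,
            class = c("accessibility_matrix", class(A)))
}

#' Quantile normalization across samples
#'
#' Forces every sample's accessibility distribution onto the common reference
#' distribution (the row-wise mean of the per-sample sorted values). Tied
#' values within a sample all receive the mean of the reference values at the
#' tied ranks, so a constant column maps to the mean of the reference
#' distribution. Idempotent.
#'
#' @param mat numeric matrix (e.g. an `accessibility_matrix`), features x samples.
#' @return A matrix of the same shape and attributes with identical sorted
#'   columns.
#' @export
quantile_normalize <- function(mat) {
  a <- attributes(mat)
  m <- as.matrix(mat)
  if (ncol(m) < 2) {
    warnf("quantile normalization needs >= 2 samples; returning input unchanged")
    return(mat)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    # average reference values over tied input values
    ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  for (at in setdiff(names(a), c("dim", "dimnames"))) attr(out, at) <- a[[at]]
  out
}

#' Within-pair discordance in accessibility
#'
#' For each meta-peak and twin pair with sibling values X1, X2, computes the
#' absolute difference `D_abs = |X1 - X2|` and the normalized discordance
#' `D_norm = |X1 - X2| / (X1 + X2)`; the latter is bounded in \[0, 1\] and is
#' the quantity used when comparing loci of different accessibility levels.
#' `D_norm` is `NA` when `X1 + X2 = 0`.
#'
#' @param mat accessibility matrix, peaks x samples (columns named by sample).
#' @param pairing a [twin_cohort()] table covering the matrix columns.
#'
#' @return A long data.frame (`peak_id`, `pair_id`, `x1`, `x2`, `d_abs`,
#'   `d_norm`) of class `discordance_table`.
#' @export
pair_discordance <- function(mat, pairing) {
  if (!inherits(pairing, "twin_cohort")) pairing <- twin_cohort(pairing$sample_id, pairing$pair_id, pairing$sibling)
  if (!all(pairing$sample_id %in% colnames(mat))) stopf("matrix is missing samples named in the pairing table")
  s1 <- sibling_samples(pairing, 1L)
  s2 <- sibling_samples(pairing, 2L)
  pid <- pair_ids(pairing)
  x1 <- mat[, s1, drop = FALSE]
  x2 <- mat[, s2, drop = FALSE]
  n_peak <- nrow(mat)
  pk <- rownames(mat)
  if (is.null(pk)) pk <- sprintf("peak_%04d", seq_len(n_peak))
  out <- data.frame(
    peak_id = rep(pk, times = length(pid)),
    pair_id = rep(pid, each = n_peak),
    x1 = as.vector(x1), x2 = as.vector(x2),
    stringsAsFactors = FALSE
  )
  out$d_abs <- abs(out$x1 - out$x2)
  s <- out$x1 + out$x2
  out$d_norm <- ifelse(s > 0, out$d_abs / s, NA_real_)
  class(out) <- c("discordance_table", "data.frame")
  out
}

#' Flag discordant chromatin sites
#'
#' Two flagging rules. `"fold_change"` flags a (peak, pair) observation when
#' the within-pair fold change exceeds `fc_threshold`, computed with a
#' pseudocount: `(max(X1,X2) + c) / (min(X1,X2) + c) > fc_threshold`.
#' `"variance"` flags a peak when its within-pair variance (mean over pairs of
#' `(X1 - X2)^2 / 2`) exceeds the between-pair variance (variance of the pair
#' means `(X1 + X2) / 2`).
#'
#' @param disc a `discordance_table` from [pair_discordance()].
#' @param rule `"fold_change"` or `"variance"`.
#' @param pseudocount pseudocount c for the fold-change rule (default 1),
#'   applied on the normalized accessibility scale.
#' @param fc_threshold fold-change cutoff (default 4).
#'
#' @return For `"fold_change"`, `disc` with a logical `discordant` column.
#'   For `"variance"`, a per-peak data.frame (`peak_id`, `within_var`,
#'   `between_var`, `discordant`).
#' @export
call_discordant_sites <- function(disc, rule = c("fold_change", "variance"),
                                  pseudocount = 1, fc_threshold = 4) {
  rule <- match.arg(rule)
  if (rule == "fold_change") {
    hi <- pmax(disc$x1, disc$x2) + pseudocount
    lo <- pmin(disc$x1, disc$x2) + pseudocount
    disc$discordant <- hi / lo > fc_threshold
    return(disc)
  }
  sp <- split(disc, disc$peak_id)
  out <- data.frame(
    peak_id = names(sp),
    within_var = vapply(sp, function(d) mean((d$x1 - d$x2)^2 / 2), numeric(1)),
    between_var = vapply(sp, function(d) var((d$x1 + d$x2) / 2), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$discordant <- out$within_var > out$between_var
  rownames(out) <- NULL
  out
}

#' Summarize per-peak values by regulatory state
#'
#' Assigns peaks to labeled regulatory-state domains by interval overlap (a
#' peak overlapping several domains contributes to each) and summarizes a
#' per-peak value within each state. When a logical `flagged` column is
#' present, also reports the fraction of domains of each state containing at
#' least one flagged peak, among domains containing any analyzed peak.
#'
#' @param values per-peak data.frame with columns `chrom`, `start`, `end`,
#'   `value`, and optionally `flagged`.
#' @param states labeled interval set (`chrom`, `start`, `end`, `name`).
#'
#' @return Per-state data.frame: `state`, `n_domains`, `n_peaks`, `mean`,
#'   `median`, and `fraction_flagged` when applicable.
#' @export
summarize_by_state <- function(values, states) {
  validate_intervals(values, "value")
  validate_intervals(states, "state")
  hp <- overlap_pairs(values, states)
  if (!nrow(hp)) {
    warnf("no peak overlaps any state domain; returning empty summary")
    return(data.frame(state = character(), n_domains = integer(), n_peaks = integer(),
                      mean = numeric(), median = numeric()))
  }
  df <- data.frame(
    state = states$name[hp$subject],
    domain = hp$subject,
    value = values$value[hp$query],
    flagged = if (!is.null(values$flagged)) values$flagged[hp$query] else NA
  )
  sp <- split(df, df$state)
  out <- data.frame(
    state = names(sp),
    n_domains = vapply(sp, function(d) length(unique(d$domain)), integer(1)),
    n_peaks = vapply(sp, nrow, integer(1)),
    mean = vapply(sp, function(d) mean(d$value, na.rm = TRUE), numeric(1)),
    median = vapply(sp, function(d) median(d$value, na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(values$flagged)) {
    out$fraction_flagged <- vapply(sp, function(d) {
      byd <- tapply(d$flagged, d$domain, any)
      mean(byd)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Compare discordance between groups of observations
#'
#' Reports the mean normalized discordance per group and two-sided Wilcoxon
#' rank-sum p-values for each group against the first (reference) group.
#' Used e.g. to contrast (peak, pair) observations with and without a somatic
#' mutation, or stratified by TFBS evidence.
#'
#' @param values numeric vector of discordance values (typically `d_norm`).
#' @param groups categorical labels, same length; the first factor level is
#'   the reference group.
#'
#' @return list with `means` (named vector, in level order) and `tests`
#'   (data.frame `group`, `p` vs the reference).
#' @export
compare_discordance_by_group <- function(values, groups) {
  groups <- as.factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  lv <- levels(groups)
  if (length(lv) < 2) stopf("need >= 2 non-empty groups")
  means <- tapply(values, groups, mean)[lv]
  ref <- values[groups == lv[1]]
  tests <- data.frame(group = lv[-1], p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(tests$group)) {
    g <- values[groups == tests$group[i]]
    if (!length(g) || !length(ref)) {
      warnf("empty group '%s'; comparison skipped", tests$group[i])
      next
    }
    tests$p[i] <- wilcox.test(g, ref, exact = FALSE)$p.value
  }
  list(means = means, tests = tests)
}
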