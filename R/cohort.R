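#' Twin cohort pairing table
#'
#' The pairing table is the backbone joining the count, allele, genotype,
#' expression and methylation matrices: it maps every sample to a twin pair
#' and a sibling slot.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param pair_id identifier of the monozygotic pair each sample belongs to.
#' @param sibling integer sibling slot within the pair, 1 or 2.
#'
#' @return A `data.frame` of class `twin_cohort` with columns `sample_id`,
#'   `pair_id`, `sibling`, one row per sample, validated so that every pair
#'   has exactly two samples occupying sibling slots 1 and 2.
#' @export
twin_cohort <- function(sample_id, pair_id, sibling) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    pair_id = as.character(pair_id),
    sibling = as.integer(sibling),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in pairing table")
  if (!all(df$sibling %in% c(1L, 2L))) stopf("sibling must be 1 or 2")
  bad <- names(which(table(df$pair_id) != 2L))
  if (length(bad)) stopf("pair(s) without exactly 2 samples: %s", paste(bad, collapse = ", "))
  slots <- tapply(df$sibling, df$pair_id, function(s) sort(s))
  if (!all(vapply(slots, function(s) identical(as.integer(s), c(1L, 2L)), logical(1)))) {
    stopf("each pair must have sibling slots 1 and 2")
  }
  df <- df[order(df$pair_id, df$sibling), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("twin_cohort", "data.frame")
  df
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Twin cohort: %d pairs (%d samples)\n",
              length(unique(x$pair_id)), nrow(x)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

## sample ids of sibling `k` per pair, in pair order
sibling_samples <- function(pairing, k) {
  sub <- pairing[pairing$sibling == k, ]
  sub$sample_id[order(sub$pair_id)]
}

pair_ids <- function(pairing) sort(unique(pairing$pair_id))
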