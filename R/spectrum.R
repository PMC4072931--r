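## The 16 dinucleotides collapse onto 10 strand-symmetric classes; the four
## palindromes (ApT, CpG, GpC, TpA) are their own reverse complement and are
## double-counted everywhere so that one-member and two-member classes are
## comparable.

revcomp2 <- function(d) {
  vapply(d, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

p_label <- function(d) paste(substr(d, 1, 1), substr(d, 2, 2), sep = "p")

.dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))

dinuc_class_label <- function(d) {
  rc <- revcomp2(d)
  lo <- pmin(d, rc); hi <- pmax(d, rc)
  ifelse(lo == hi, p_label(lo), paste(p_label(lo), p_label(hi), sep = ":"))
}

.dinuc_class_map <- setNames(dinuc_class_label(.dinucs), .dinucs)
.dinuc_classes <- sort(unique(.dinuc_class_map))
.palindromic_classes <- .dinuc_classes[!grepl(":", .dinuc_classes)]

#' Strand-collapsed dinucleotide class
#'
#' Maps a 2-mer and its reverse complement to the same class label; the
#' canonical label is built from the lexicographically smaller member
#' (e.g. `CT` -> `ApG:CpT`). Palindromic dinucleotides (`ApT`, `CpG`, `GpC`,
#' `TpA`) form single-member classes.
#'
#' @param dinuc character vector of 2-mers over A/C/G/T.
#' @return character vector of class labels.
#' @export
collapse_dinucleotide <- function(dinuc) {
  bad <- !dinuc %in% .dinucs
  if (any(bad)) stopf("not a dinucleotide over ACGT: %s", paste(dinuc[bad], collapse = ","))
  unname(.dinuc_class_map[dinuc])
}

#' The 10 dinucleotide classes
#' @return character vector of the 10 class labels (palindromes flagged in
#'   the `palindromic` attribute).
#' @export
dinuc_classes <- function() {
  structure(.dinuc_classes, palindromic = .dinuc_classes %in% .palindromic_classes)
}

new_spectrum <- function(counts16) {
  cls <- tapply(counts16, .dinuc_class_map[names(counts16)], sum)
  out <- setNames(numeric(length(.dinuc_classes)), .dinuc_classes)
  out[names(cls)] <- cls
  out[.palindromic_classes] <- 2 * out[.palindromic_classes]
  structure(out, class = "dinuc_spectrum")
}

#' @export
print.dinuc_spectrum <- function(x, ...) {
  cat("Dinucleotide class spectrum (palindromes double-counted):\n")
  print(unclass(x))
  invisible(x)
}

#' Count dinucleotide occurrences within regions
#'
#' Every 2-bp window fully inside a region contributes one count to its
#' strand-collapsed class; palindromic class totals are then doubled so that
#' single-member classes are on the same footing as two-member classes.
#'
#' @param sequence genome sequence: a named character vector or
#'   [Biostrings::DNAStringSet] per contig.
#' @param regions interval data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open); `NULL` counts whole contigs.
#' @return named numeric vector of class `dinuc_spectrum` over the 10
#'   classes.
#' @export
count_sequence_dinucleotides <- function(sequence, regions = NULL) {
  seqs <- as_dnastringset(sequence)
  if (is.null(regions)) {
    parts <- seqs
  } else {
    validate_intervals(regions, "region")
    if (!all(regions$chrom %in% names(seqs))) stopf("region on unknown contig")
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    if (any(regions$end > lens[regions$chrom])) stopf("region beyond contig bounds")
    parts <- Biostrings::DNAStringSet(seqs[regions$chrom],
                                      start = regions$start + 1L,
                                      end = regions$end)
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(parts, width = 2))
  new_spectrum(counts)
}

as_dnastringset <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) return(sequence)
  if (is.character(sequence)) {
    if (is.null(names(sequence))) names(sequence) <- sprintf("contig_%d", seq_along(sequence))
    return(Biostrings::DNAStringSet(sequence))
  }
  stopf("sequence must be a DNAStringSet or named character vector")
}

#' Count the dinucleotide contexts of variants
#'
#' For each variant the two reference-context dinucleotides are tallied: the
#' -1 base with the variant base (-1pV) and the variant base with the +1 base
#' (Vp+1). Palindromic class totals are doubled. Variants at contig edges
#' contribute only the available side.
#'
#' @param calls call table with `chrom`, `pos` (0-based), `ref`.
#' @param sequence genome sequence (see [count_sequence_dinucleotides()]).
#' @return a `dinuc_spectrum` of substituted-dinucleotide counts.
#' @export
count_variant_dinucleotides <- function(calls, sequence) {
  seqs <- as_dnastringset(sequence)
  counts <- setNames(numeric(length(.dinucs)), .dinucs)
  if (nrow(calls)) {
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    chars <- lapply(seqs, as.character)
    edge <- 0L
    for (i in seq_len(nrow(calls))) {
      s <- chars[[calls$chrom[i]]]
      p1 <- calls$pos[i] + 1L  # 1-based position of the variant base
      base <- substr(s, p1, p1)
      if (!is.na(calls$ref[i]) && base != calls$ref[i]) {
        warnf("reference mismatch at %s:%d (genome %s, call %s)",
              calls$chrom[i], calls$pos[i], base, calls$ref[i])
      }
      if (p1 > 1) {
        d <- substr(s, p1 - 1L, p1); counts[d] <- counts[d] + 1
      } else edge <- edge + 1L
      if (p1 < lens[calls$chrom[i]]) {
        d <- substr(s, p1, p1 + 1L); counts[d] <- counts[d] + 1
      } else edge <- edge + 1L
    }
    if (edge) message(edge, " context side(s) beyond contig edge; partial contribution")
  }
  new_spectrum(counts)
}

#' Observed-to-expected ratios of base-change classes in TFBSs
#'
#' The frequency of each strand-collapsed base-change class among TFBS calls
#' divided by its frequency among open-chromatin (background) calls;
#' frequencies sum to one within each set. Calls without a typed base change
#' (direction unclassified) are excluded.
#'
#' @param calls_tfbs,calls_open typed call tables ([classify_base_change()])
#'   for the TFBS and background sets.
#' @return data.frame `class`, `observed_freq`, `expected_freq`, `ratio`
#'   (NA-flagged where the background class is empty).
#' @export
base_change_oe <- function(calls_tfbs, calls_open) {
  bt <- calls_tfbs$base_change[!is.na(calls_tfbs$base_change)]
  bo <- calls_open$base_change[!is.na(calls_open$base_change)]
  if (!length(bt)) stopf("no typed TFBS calls")
  if (!length(bo)) stopf("no typed background calls")
  lev <- sort(unique(c(bt, bo)))
  ft <- table(factor(bt, lev)) / length(bt)
  fo <- table(factor(bo, lev)) / length(bo)
  data.frame(
    class = lev,
    observed_freq = as.numeric(ft),
    expected_freq = as.numeric(fo),
    ratio = ifelse(as.numeric(fo) > 0, as.numeric(ft) / as.numeric(fo), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Relative enrichment of dinucleotides in TFBSs
#'
#' Per class d: `(n_d^TFBS / n_d^bg) / (N^TFBS / N^bg)` where N are all-class
#' totals — the occurrence ratio normalized by the overall size ratio. The
#' background may be the surrounding open chromatin or the whole genome.
#' Palindrome double-counting cancels within each class's ratio.
#'
#' @param spectrum_tfbs,spectrum_background `dinuc_spectrum` objects computed
#'   with identical rules.
#' @return data.frame `class`, `n_tfbs`, `n_background`, `ratio` (NA where
#'   the background count is zero).
#' @export
dinuc_relative_enrichment <- function(spectrum_tfbs, spectrum_background) {
  nt <- as.numeric(spectrum_tfbs); nb <- as.numeric(spectrum_background)
  size_ratio <- sum(nt) / sum(nb)
  data.frame(
    class = .dinuc_classes,
    n_tfbs = nt, n_background = nb,
    ratio = ifelse(nb > 0, (nt / nb) / size_ratio, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Observed-to-expected ratio of substituted dinucleotides in TFBSs
#'
#' The relative enrichment of substituted dinucleotides in TFBSs divided by
#' the relative enrichment of the dinucleotides themselves:
#' `[(sub_d^T/sub_d^O)/(SUB^T/SUB^O)] / [(n_d^T/n_d^O)/(N^T/N^O)]`.
#' This is the CpG-depletion statistic: a ratio ~0.2 for CpG means CpGs are
#' substituted five-fold less often than their TFBS enrichment predicts.
#'
#' @param var_tfbs,var_open variant-context spectra
#'   ([count_variant_dinucleotides()]) in TFBSs / background.
#' @param seq_tfbs,seq_open sequence spectra
#'   ([count_sequence_dinucleotides()]) over the identical region sets.
#' @return data.frame `class`, `sub_enrichment`, `seq_enrichment`, `ratio`.
#' @export
substituted_dinuc_oe <- function(var_tfbs, var_open, seq_tfbs, seq_open) {
  sub_enr <- dinuc_relative_enrichment(var_tfbs, var_open)
  seq_enr <- dinuc_relative_enrichment(seq_tfbs, seq_open)
  data.frame(
    class = .dinuc_classes,
    sub_enrichment = sub_enr$ratio,
    seq_enrichment = seq_enr$ratio,
    ratio = ifelse(!is.na(sub_enr$ratio) & !is.na(seq_enr$ratio) & seq_enr$ratio > 0,
                   sub_enr$ratio / seq_enr$ratio, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' CpG-context substitution spectrum O/E
#'
#' Restricted to calls whose reference CpG is substituted (a C followed by G,
#' or a G preceded by C, strand-collapsed), classes `CpG>TpG`, `CpG>ApG`,
#' `CpG>GpG`. Ratios are the TFBS class frequencies over the open-chromatin
#' class frequencies, as in [base_change_oe()].
#'
#' @param calls_tfbs,calls_open call tables with `chrom`, `pos`, `ref`, `alt`.
#' @param sequence genome sequence.
#' @return data.frame `class`, `observed_freq`, `expected_freq`, `ratio`.
#' @export
cpg_change_oe <- function(calls_tfbs, calls_open, sequence) {
  lt <- cpg_change_label(calls_tfbs, sequence)
  lo <- cpg_change_label(calls_open, sequence)
  lt <- lt[!is.na(lt)]; lo <- lo[!is.na(lo)]
  if (!length(lt) || !length(lo)) stopf("no CpG-context calls in one of the sets")
  lev <- c("CpG>ApG", "CpG>GpG", "CpG>TpG")
  ft <- table(factor(lt, lev)) / length(lt)
  fo <- table(factor(lo, lev)) / length(lo)
  data.frame(class = lev, observed_freq = as.numeric(ft),
             expected_freq = as.numeric(fo),
             ratio = ifelse(as.numeric(fo) > 0, as.numeric(ft) / as.numeric(fo), NA_real_),
             stringsAsFactors = FALSE)
}

## label per call: "CpG>XpG" when the substituted base sits in a reference
## CpG (either strand), NA otherwise
cpg_change_label <- function(calls, sequence) {
  if (!nrow(calls)) return(character(0))
  seqs <- as_dnastringset(sequence)
  chars <- lapply(seqs, as.character)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  out <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- chars[[calls$chrom[i]]]
    p1 <- calls$pos[i] + 1L
    ref <- calls$ref[i]; alt <- calls$alt[i]
    if (ref == "C" && p1 < lens[calls$chrom[i]] && substr(s, p1 + 1L, p1 + 1L) == "G") {
      out[i] <- sprintf("CpG>%spG", alt)
    } else if (ref == "G" && p1 > 1 && substr(s, p1 - 1L, p1 - 1L) == "C") {
      # CpG on the reverse strand; collapse G>alt to C>comp(alt)
      out[i] <- sprintf("CpG>%spG", comp_base(alt))
    }
  }
  out
}

#' Filter ChIP-seq peaks by summit concentration
#'
#' The summit of a peak is the position covered by the maximum number of its
#' supporting ChIP tags (leftmost on ties). A peak is retained only when at
#' least 80% (by default) of its tags overlap the summit position — peaks
#' with diffuse tag distributions, unlikely to hold a single focused binding
#' site, are discarded. Peaks with zero tags are discarded.
#'
#' @param peaks peak table with `peak_id`, `chrom`, `start`, `end`.
#' @param tags per-tag intervals: `peak_id`, `start`, `end` (0-based).
#' @param min_frac minimum fraction of tags overlapping the summit
#'   (default 0.8, inclusive).
#' @return `peaks` restricted to retained rows, with `summit` (0-based
#'   position) and `tag_frac` columns.
#' @export
filter_chip_peaks_by_summit <- function(peaks, tags, min_frac = 0.8) {
  out <- peaks
  out$summit <- NA_integer_
  out$tag_frac <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    tg <- tags[tags$peak_id == peaks$peak_id[i], ]
    if (!nrow(tg)) next
    ir <- IRanges::IRanges(start = tg$start + 1L, end = tg$end)
    cov <- IRanges::coverage(ir)
    v <- as.integer(cov)
    summit1 <- which.max(v)  # leftmost maximum
    out$summit[i] <- summit1 - 1L
    out$tag_frac[i] <- sum(tg$start <= out$summit[i] & tg$end > out$summit[i]) / nrow(tg)
  }
  drop0 <- is.na(out$summit)
  if (any(drop0)) message(sum(drop0), " peak(s) with zero tags discarded")
  keep <- !drop0 & out$tag_frac >= min_frac
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
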