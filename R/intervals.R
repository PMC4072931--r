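## Interval plumbing. All data.frame interval tables in this package use
## BED-style 0-based half-open coordinates [start, end); GRanges (1-based,
## closed) only appear transiently inside these helpers.

validate_intervals <- function(df, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stopf("%s table needs columns chrom,start,end", what)
  if (nrow(df) && any(df$start >= df$end)) stopf("malformed %s: start >= end", what)
  if (nrow(df) && any(df$start < 0)) stopf("malformed %s: negative start", what)
  invisible(df)
}

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

as_bed0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read / write BED interval tables
#'
#' Thin wrappers over [rtracklayer::import()] / [rtracklayer::export()]
#' returning plain 0-based half-open `data.frame`s (`chrom`, `start`, `end`,
#' plus `name` when present).
#'
#' @param file path to a BED file.
#' @rdname bed_io
#' @return `read_bed()`: a data.frame; `write_bed()`: the file path, invisibly.
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  df <- as_bed0(gr)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  str <- as.character(GenomicRanges::strand(gr))
  if (any(str != "*")) df$strand <- str
  df
}

#' @param df 0-based half-open interval data.frame; optional `name`/`strand`
#'   columns are carried into the BED columns.
#' @rdname bed_io
#' @export
write_bed <- function(df, file) {
  validate_intervals(df)
  gr <- as_granges0(df)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$strand)) GenomicRanges::strand(gr) <- df$strand
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

## overlap between two 0-based interval tables; returns hit index pairs
overlap_pairs <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  data.frame(query = S4Vectors::queryHits(hits), subject = S4Vectors::subjectHits(hits))
}

## peak index containing each (chrom, pos) point, NA when outside all peaks
locate_in_peaks <- function(chrom, pos, peaks) {
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1)
  hp <- overlap_pairs(pts, peaks)
  out <- rep(NA_integer_, length(pos))
  out[hp$query] <- hp$subject
  out
}
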