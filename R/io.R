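## Flat-file interfaces. Every pipeline stage couples to the next through
## these files only; TSVs are plain tab-separated with headers, BED via
## rtracklayer, FASTA via Biostrings, variants as minimal VCF 4.2.

write_tsv <- function(df, file, row_names = FALSE) {
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(file)
}

read_tsv <- function(file, ...) read.delim(file, stringsAsFactors = FALSE, ...)

#' Write / read a sample-by-feature matrix TSV
#'
#' Matrices (counts, accessibility, expression, genotypes) are stored with
#' row names in the first column.
#'
#' @param m matrix with dimnames.
#' @param file path.
#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, file)
}

#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read genome FASTA
#' @param sequences named character vector of contig sequences.
#' @param file path.
#' @rdname fasta_io
#' @export
write_genome_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), file)
  invisible(file)
}

#' @rdname fasta_io
#' @export
read_genome_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*", "", names(out))
  out
}

#' Write variant calls as minimal VCF 4.2
#'
#' One record per call with INFO keys: `SOMATIC` (flag), `FETP` (Fisher p),
#' `PAIR`, `DIR` (direction), `BCC` (strand-collapsed base-change class),
#' `MAF` (pooled minor-allele frequency). Positions are converted to the
#' 1-based VCF convention.
#'
#' @param calls a call table from [call_somatic_mutations()] /
#'   [call_polymorphisms()], optionally typed and direction-annotated.
#' @param file output path.
#' @rdname vcf_io
#' @export
write_variant_vcf <- function(calls, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Within-pair somatic mutation\">",
    "##INFO=<ID=FETP,Number=1,Type=Float,Description=\"Fisher exact test p-value\">",
    "##INFO=<ID=PAIR,Number=1,Type=String,Description=\"Twin pair carrying the mutation\">",
    "##INFO=<ID=DIR,Number=1,Type=String,Description=\"Direction of accessibility change\">",
    "##INFO=<ID=BCC,Number=1,Type=String,Description=\"Strand-collapsed base change class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Pooled minor allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      kv <- character(0)
      if (calls$class[i] == "somatic_mutation") {
        kv <- c(kv, "SOMATIC",
                sprintf("FETP=%.6g", calls$p_value[i]),
                sprintf("PAIR=%s", calls$pair_id[i]))
      } else {
        kv <- c(kv, sprintf("MAF=%.6g", calls$pooled_maf[i]))
      }
      if (!is.null(calls$direction) && !is.na(calls$direction[i])) {
        kv <- c(kv, sprintf("DIR=%s", calls$direction[i]))
      }
      if (!is.null(calls$base_change) && !is.na(calls$base_change[i])) {
        kv <- c(kv, sprintf("BCC=%s", calls$base_change[i]))
      }
      paste(kv, collapse = ";")
    }, character(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       calls$chrom, calls$pos + 1L, calls$ref, calls$alt, info), con)
  }
  invisible(file)
}

#' @rdname vcf_io
#' @return `read_variant_vcf()`: a call table with 0-based `pos` and the
#'   INFO keys unpacked (`class`, `p_value`, `pair_id`, `direction`,
#'   `base_change`, `pooled_maf`).
#' @export
read_variant_vcf <- function(file) {
  lines <- readLines(file)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), class = character(), p_value = numeric(),
                      pair_id = character(), direction = character(),
                      base_change = character(), pooled_maf = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[`, character(1), 8)
  val <- function(key) {
    vapply(info, function(x) {
      m <- regmatches(x, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), x, perl = TRUE))
      if (!length(m)) NA_character_ else sub(paste0("^;?", key, "="), "", m)
    }, character(1), USE.NAMES = FALSE)
  }
  somatic <- grepl("(^|;)SOMATIC(;|$)", info)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)) - 1L,
    ref = vapply(f, `[`, character(1), 4),
    alt = vapply(f, `[`, character(1), 5),
    class = ifelse(somatic, "somatic_mutation", "polymorphism"),
    p_value = as.numeric(val("FETP")),
    pair_id = val("PAIR"),
    direction = val("DIR"),
    base_change = val("BCC"),
    pooled_maf = as.numeric(val("MAF")),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated cohort to a directory
#'
#' Materializes the synthetic genome, cohort, expression and methylation as
#' the flat files the pipeline stages read: `genome.fa`, `peaks.bed`,
#' `tfbs.bed`, `states.bed`, `tss.bed`, `counts.tsv`, `alleles.tsv`,
#' `pairs.tsv`, `genotypes.tsv`, `snp_positions.tsv`, `expression.tsv`,
#' `methylation.tsv`, and the ground truth under `truth/`.
#'
#' @param assets `genome_assets`.
#' @param cohort `twin_cohort_sim`.
#' @param expr result of [generate_expression()] (optional).
#' @param meth result of [generate_methylation()] (optional).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(assets, cohort, expr = NULL, meth = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_genome_fasta(assets$sequences, file.path(dir, "genome.fa"))
  pk <- assets$peaks; pk$name <- pk$peak_id
  write_bed(pk, file.path(dir, "peaks.bed"))
  tf <- assets$tfbs; tf$name <- tf$tfbs_id
  write_bed(tf, file.path(dir, "tfbs.bed"))
  write_bed(assets$states, file.path(dir, "states.bed"))
  ts <- data.frame(chrom = assets$tss$chrom, start = assets$tss$pos,
                   end = assets$tss$pos + 1L, name = assets$tss$gene_id,
                   strand = assets$tss$strand, stringsAsFactors = FALSE)
  write_bed(ts, file.path(dir, "tss.bed"))
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_tsv(cohort$alleles, file.path(dir, "alleles.tsv"))
  write_tsv(as.data.frame(cohort$pairing), file.path(dir, "pairs.tsv"))
  write_matrix_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(cohort$snp_positions, file.path(dir, "snp_positions.tsv"))
  if (!is.null(expr)) {
    write_matrix_tsv(expr$expression, file.path(dir, "expression.tsv"))
    write_tsv(expr$truth, file.path(dir, "truth", "expression_coupling.tsv"))
  }
  if (!is.null(meth)) {
    write_tsv(meth$methylation, file.path(dir, "methylation.tsv"))
    write_tsv(meth$truth, file.path(dir, "truth", "regulated_cpgs.tsv"))
  }
  write_tsv(cohort$truth$mutations, file.path(dir, "truth", "mutations.tsv"))
  write_tsv(cohort$truth$polymorphisms, file.path(dir, "truth", "polymorphisms.tsv"))
  write_tsv(cohort$truth$qtls, file.path(dir, "truth", "qtls.tsv"))
  invisible(dir)
}
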