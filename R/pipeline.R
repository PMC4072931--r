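#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its default:
#' Fisher p cutoff 1e-3, >= 10 high-quality reads per strand, pooled MAF
#' 0.01, one-strand fraction 0.90, fold change 4 (pseudocount 1), top
#' variance fraction 0.01, cis window 1 Mb, QTL FDR 0.01, SNP-association
#' FDR 0.05, promoter window 2 kb, 10,000 permutations.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    n_pairs = 36,
    contig_length = 1e6,
    n_contigs = 1,
    peak_density = 0.045,
    tfbs_cpg_boost = 4,
    depth = 200,
    dispersion = 0.05,
    n_mutations = 20,
    n_qtls = 3,
    qtl_beta = 0.3,
    p_threshold = 1e-3,
    min_hq_per_strand = 10,
    maf = 0.01,
    strand_frac = 0.90,
    fc = 4,
    pseudocount = 1,
    top_frac = 0.01,
    cis_window = 1e6,
    fdr_qtl = 0.01,
    fdr_snp = 0.05,
    window = 2000,
    n_perm = 10000,
    coupling_strength = 1.5,
    expr_noise_sd = 0.25,
    regulated_fraction = 0.3,
    meth_delta = 0.5,
    contigs = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stopf("invalid config: %s", msg)
  chk(cfg$p_threshold > 0 && cfg$p_threshold <= 1, "p_threshold in (0,1]")
  chk(cfg$maf >= 0 && cfg$maf <= 0.5, "maf in [0,0.5]")
  chk(cfg$strand_frac > 0.5 && cfg$strand_frac <= 1, "strand_frac in (0.5,1]")
  chk(cfg$top_frac > 0 && cfg$top_frac <= 1, "top_frac in (0,1]")
  chk(cfg$fdr_qtl > 0 && cfg$fdr_qtl < 1, "fdr_qtl in (0,1)")
  chk(cfg$fdr_snp > 0 && cfg$fdr_snp < 1, "fdr_snp in (0,1)")
  chk(cfg$fc > 1, "fc > 1")
  chk(cfg$min_hq_per_strand >= 0, "min_hq_per_strand >= 0")
  chk(cfg$window >= 0, "window >= 0")
  chk(cfg$n_perm >= 1, "n_perm >= 1")
  invisible(cfg)
}

stage <- function(name, expr) {
  message(format(Sys.time(), "%H:%M:%S"), " [", name, "] running")
  tryCatch(expr, error = function(e) stopf("stage %s: %s", name, conditionMessage(e)))
}

#' Run the full twin-discordance pipeline
#'
#' Executes every stage in dependency order on a simulated cohort:
#' `simulate` (genome + cohort + expression + methylation files),
#' `quantify` (normalization, quantile normalization, discordance, state
#' summary), `callmut` (somatic mutations + peak context), `callsnp`
#' (polymorphisms + SNP-accessibility association), `spectrum`
#' (base-change and dinucleotide O/E ratios), `qtl` (variability-QTL
#' mapping), and `integrate` (expression coupling and CpG methylation
#' comparison). All coupling between stages is through the files in the run
#' directory; a `manifest.json` records the config hash, seed, and per-stage
#' row counts, and re-running the same config reproduces it exactly.
#'
#' @param config a `run_config` from [default_config()].
#' @param out_dir run directory (created).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "sim")
  manifest <- list(seed = config$seed, stages = list())
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  ## -- simulate ------------------------------------------------------
  if (config$simulate) stage("simulate", {
    assets <- generate_genome(n_contigs = config$n_contigs,
                              contig_length = config$contig_length,
                              peak_density = config$peak_density,
                              tfbs_cpg_boost = config$tfbs_cpg_boost,
                              seed = child_seed(config$seed, 1))
    cohort <- generate_twin_cohort(assets, n_pairs = config$n_pairs,
                                   depth = config$depth,
                                   dispersion = config$dispersion,
                                   n_mutations = config$n_mutations,
                                   n_qtls = config$n_qtls,
                                   qtl_beta = config$qtl_beta,
                                   seed = child_seed(config$seed, 2))
    expr <- generate_expression(cohort, assets,
                                coupling_strength = config$coupling_strength,
                                noise_sd = config$expr_noise_sd,
                                seed = child_seed(config$seed, 3))
    meth <- generate_methylation(assets,
                                 regulated_fraction = config$regulated_fraction,
                                 delta = config$meth_delta,
                                 seed = child_seed(config$seed, 4))
    write_cohort(assets, cohort, expr, meth, sim_dir)
    manifest$stages$simulate <- list(
      peaks = nrow(assets$peaks),
      samples = nrow(cohort$pairing),
      allele_rows = nrow(cohort$alleles),
      genes = nrow(expr$expression),
      cpgs = nrow(meth$methylation))
  })

  ## -- quantify ------------------------------------------------------
  stage("quantify", {
    for (f in c("pairs.tsv", "counts.tsv", "peaks.bed")) {
      if (!file.exists(file.path(sim_dir, f))) stopf("missing input %s", f)
    }
    pairs_df <- read_tsv(file.path(sim_dir, "pairs.tsv"))
    pairing <- twin_cohort(pairs_df$sample_id, pairs_df$pair_id, pairs_df$sibling)
    counts <- read_matrix_tsv(file.path(sim_dir, "counts.tsv"))
    pk <- read_bed(file.path(sim_dir, "peaks.bed"))
    pk$peak_id <- pk$name
    genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
    A <- normalize_accessibility(counts, pk, sum(nchar(genome)))
    Aq <- quantile_normalize(A)
    write_matrix_tsv(Aq, file.path(out_dir, "accessibility.tsv"))
    disc <- pair_discordance(Aq, pairing)
    disc_fc <- call_discordant_sites(disc, "fold_change",
                                     pseudocount = config$pseudocount,
                                     fc_threshold = config$fc)
    write_tsv(disc_fc, file.path(out_dir, "discordance.tsv"))
    states <- read_bed(file.path(sim_dir, "states.bed"))
    pkval <- pk
    pkval$value <- tapply(disc$d_norm, factor(disc$peak_id, pk$peak_id), mean, na.rm = TRUE)
    pkval$flagged <- tapply(disc_fc$discordant, factor(disc_fc$peak_id, pk$peak_id), any)
    st <- summarize_by_state(pkval, states)
    write_tsv(st, file.path(out_dir, "state_summary.tsv"))
    manifest$stages$quantify <- list(peaks = nrow(pk),
                                      discordance_rows = nrow(disc),
                                      states = nrow(st))
  })

  ## -- callmut -------------------------------------------------------
  pairing <- {
    pairs_df <- read_tsv(file.path(sim_dir, "pairs.tsv"))
    twin_cohort(pairs_df$sample_id, pairs_df$pair_id, pairs_df$sibling)
  }
  alleles <- read_tsv(file.path(sim_dir, "alleles.tsv"))
  pk <- read_bed(file.path(sim_dir, "peaks.bed")); pk$peak_id <- pk$name
  Aq <- read_matrix_tsv(file.path(out_dir, "accessibility.tsv"))

  stage("callmut", {
    muts <- call_somatic_mutations(alleles, pairing,
                                   p_threshold = config$p_threshold,
                                   min_hq_per_strand = config$min_hq_per_strand)
    muts <- classify_base_change(muts)
    muts <- mutation_direction(muts, Aq, pk, pairing)
    ctx <- annotate_mutation_peak_context(muts, pk)
    write_variant_vcf(muts, file.path(out_dir, "mutations.vcf"))
    write_tsv(ctx$calls, file.path(out_dir, "context.tsv"))
    manifest$stages$callmut <- list(calls = nrow(muts))
  })

  stage("callsnp", {
    muts <- read_variant_vcf(file.path(out_dir, "mutations.vcf"))
    snps <- call_polymorphisms(alleles, pairing, somatic_calls = muts,
                               maf_threshold = config$maf,
                               strand_frac = config$strand_frac,
                               contigs = config$contigs)
    snps <- classify_base_change(snps)
    write_variant_vcf(snps, file.path(out_dir, "polymorphisms.vcf"))
    if (nrow(snps)) {
      dos <- snp_dosage_from_alleles(alleles, snps, pairing$sample_id)
      assoc <- associate_snp_accessibility(dos, snps, Aq, pk, fdr = config$fdr_snp)
      write_tsv(assoc, file.path(out_dir, "snp_associations.tsv"))
    }
    manifest$stages$callsnp <- list(calls = nrow(snps))
  })

  ## -- spectrum ------------------------------------------------------
  stage("spectrum", {
    genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
    tfbs <- read_bed(file.path(sim_dir, "tfbs.bed"))
    muts <- read_variant_vcf(file.path(out_dir, "mutations.vcf"))
    snps <- read_variant_vcf(file.path(out_dir, "polymorphisms.vcf"))
    open_bg <- open_minus_tfbs(pk, tfbs)
    seq_tfbs <- count_sequence_dinucleotides(genome, tfbs)
    seq_open <- count_sequence_dinucleotides(genome, open_bg)
    enr <- dinuc_relative_enrichment(seq_tfbs, seq_open)
    write_tsv(enr, file.path(out_dir, "dinuc_enrichment.tsv"))
    sp <- data.frame(class = names(unclass(seq_tfbs)),
                     tfbs = as.numeric(seq_tfbs), open = as.numeric(seq_open))
    write_tsv(sp, file.path(out_dir, "spectrum.tsv"))
    all_calls <- rbind(muts[, c("chrom", "pos", "ref", "alt", "base_change")],
                       snps[, c("chrom", "pos", "ref", "alt", "base_change")])
    in_tfbs <- !is.na(locate_in_peaks(all_calls$chrom, all_calls$pos, tfbs))
    oe <- NULL
    if (sum(in_tfbs & !is.na(all_calls$base_change)) > 0 &&
        sum(!in_tfbs & !is.na(all_calls$base_change)) > 0) {
      oe <- base_change_oe(all_calls[in_tfbs, ], all_calls[!in_tfbs, ])
      write_tsv(oe, file.path(out_dir, "oe_ratios.tsv"))
    }
    var_tfbs <- count_variant_dinucleotides(all_calls[in_tfbs, ], genome)
    var_open <- count_variant_dinucleotides(all_calls[!in_tfbs, ], genome)
    sub_oe <- substituted_dinuc_oe(var_tfbs, var_open, seq_tfbs, seq_open)
    write_tsv(sub_oe, file.path(out_dir, "substituted_dinuc_oe.tsv"))
    manifest$stages$spectrum <- list(
      tfbs_calls = sum(in_tfbs), open_calls = sum(!in_tfbs),
      oe_rows = if (is.null(oe)) 0L else nrow(oe))
  })

  ## -- qtl -----------------------------------------------------------
  stage("qtl", {
    disc <- read_tsv(file.path(out_dir, "discordance.tsv"))
    genotypes <- read_matrix_tsv(file.path(sim_dir, "genotypes.tsv"))
    snp_pos <- read_tsv(file.path(sim_dir, "snp_positions.tsv"))
    top <- select_top_variance_loci(disc, fraction = config$top_frac)
    qtl <- map_variability_qtl(disc, genotypes, snp_pos, pk, peak_ids = top,
                               cis_window = config$cis_window,
                               fdr = config$fdr_qtl, maf_min = config$maf)
    write_tsv(qtl, file.path(out_dir, "qtl_associations.tsv"))
    manifest$stages$qtl <- list(selected_peaks = length(top),
                                 tests = nrow(qtl),
                                 significant = sum(qtl$significant))
  })

  ## -- integrate -----------------------------------------------------
  stage("integrate", {
    expr <- read_matrix_tsv(file.path(sim_dir, "expression.tsv"))
    tssb <- read_bed(file.path(sim_dir, "tss.bed"))
    tss <- data.frame(gene_id = tssb$name, chrom = tssb$chrom, pos = tssb$start,
                      strand = tssb$strand, stringsAsFactors = FALSE)
    disc <- read_tsv(file.path(out_dir, "discordance.tsv"))
    de <- within_pair_expression_diff(quantile_normalize(expr), pairing)
    links <- link_genes_to_peaks(tss, pk, window = config$window)
    dm <- matrix(NA_real_, nrow(pk), ncol(de),
                 dimnames = list(pk$peak_id, colnames(de)))
    dm[cbind(match(disc$peak_id, pk$peak_id), match(disc$pair_id, colnames(dm)))] <- disc$d_norm
    gi <- match(links$gene_id, rownames(de))
    x <- as.vector(dm[links$peak_id, , drop = FALSE])
    y <- as.vector(de[gi, , drop = FALSE])
    ptest <- tertile_permutation_test(x, y, n_perm = config$n_perm,
                                   seed = child_seed(config$seed, 5))
    coupling <- data.frame(statistic = ptest$statistic, p = ptest$p, n_perm = ptest$n_perm)
    write_tsv(coupling, file.path(out_dir, "expression_coupling.tsv"))

    meth <- read_tsv(file.path(sim_dir, "methylation.tsv"))
    muts <- read_variant_vcf(file.path(out_dir, "mutations.vcf"))
    snps <- read_variant_vcf(file.path(out_dir, "polymorphisms.vcf"))
    meth$status <- cpg_status(meth, muts, snps)
    cmp <- cpg_differential_methylation_compare(meth)
    write_tsv(cmp$summary, file.path(out_dir, "methylation_summary.tsv"))
    if (!is.null(cmp$tests)) write_tsv(cmp$tests, file.path(out_dir, "methylation_tests.tsv"))
    manifest$stages$integrate <- list(linked_genes = nrow(links),
                                       coupling_p = ptest$p,
                                       cpgs = nrow(meth))
  })

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## open chromatin surrounding TFBSs: peaks minus their TFBS sub-intervals
open_minus_tfbs <- function(peaks, tfbs) {
  gr <- GenomicRanges::setdiff(as_granges0(peaks), as_granges0(tfbs))
  as_bed0(gr)
}

## substitution status of each CpG: mutated / polymorphic / non_substituted.
## A CpG covers two bases; a variant hitting either base substitutes it.
cpg_status <- function(meth, muts, snps) {
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  k1 <- key(meth$chrom, meth$pos)
  k2 <- key(meth$chrom, meth$pos + 1L)
  km <- key(muts$chrom, muts$pos)
  ks <- key(snps$chrom, snps$pos)
  status <- rep("non_substituted", nrow(meth))
  status[k1 %in% ks | k2 %in% ks] <- "polymorphic"
  status[k1 %in% km | k2 %in% km] <- "mutated"
  status
}
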