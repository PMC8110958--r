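# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# full-scale synthetic cohort emulating the study design (381 precursors,
# 73 planted SNPs in 50 precursors, 23 samples)
full_cohort <- function() {
  if (is.null(.fix$full)) .fix$full <- simulate_cohort(sim_config(seed = 1))
  .fix$full
}

full_ingest <- function() {
  if (is.null(.fix$full_ingest)) {
    sim <- full_cohort()
    vs <- read_vcf(sim$paths$vcf)
    ann <- attach_hairpins(read_mirna_gff(sim$paths$gff),
                           sim$paths$hairpin_fasta)
    .fix$full_ingest <- list(sim = sim, vs = vs, ann = ann,
                             calls = classify_variants(vs, ann))
  }
  .fix$full_ingest
}

# compact cohort for pipeline-level tests
small_config <- function(seed = 2, frac_minus_strand = 0.5) {
  sim_config(seed = seed, n_precursors = 60, frac_minus_strand = frac_minus_strand,
             n_seed_snps = 2, n_mature_snps = 4, n_premirna_snps = 14,
             n_snp_precursors = 15, n_transitions_mature = 4,
             n_transitions_premirna = 10, n_stem_disrupt = 4,
             n_loop_neutral = 3, n_indels = 3, n_lowdp = 2,
             n_background_snps = 40, n_utr_genes = 200,
             n_common_sites = 8, n_lost_sites = 12, n_gained_sites = 6,
             n_go_terms = 15)
}

small_report <- function() {
  if (is.null(.fix$small)) {
    sim <- simulate_cohort(small_config())
    cfg <- pipeline_config(vcf = sim$paths$vcf, gff = sim$paths$gff,
                           hairpin_fasta = sim$paths$hairpin_fasta,
                           utr_fasta = sim$paths$utr_fasta,
                           go_tsv = sim$paths$go_tsv,
                           capture_bed = sim$paths$capture_bed)
    .fix$small <- list(sim = sim, cfg = cfg,
                       report = run_pipeline(cfg, quiet = TRUE))
  }
  .fix$small
}

# hand-written VCF with controllable DP/GQ/alleles
write_test_vcf <- function(path, records, samples = c("s1", "s2")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (r in records)
    lines <- c(lines, paste(c(if (is.null(r$chrom)) "chr1" else r$chrom,
                              r$pos, ".", r$ref, r$alt,
                              "99", "PASS", paste0("DP=", r$dp), "GT:GQ",
                              r$gt), collapse = "\t"))
  writeLines(lines, path)
  path
}

# minimal two-precursor GFF3 (one per strand) with one mature each
write_test_gff <- function(path,
                           pre = list(
                             list(id = "mir-plus", chrom = "chr1", start = 101,
                                  end = 180, strand = "+", m_start = 111,
                                  m_end = 132),
                             list(id = "mir-minus", chrom = "chr1", start = 301,
                                  end = 380, strand = "-", m_start = 351,
                                  m_end = 372))) {
  lines <- "##gff-version 3"
  for (i in seq_along(pre)) {
    p <- pre[[i]]
    lines <- c(lines,
      paste(p$chrom, "t", "miRNA_primary_transcript", p$start, p$end, ".",
            p$strand, ".", sprintf("ID=MI%03d;Name=%s", i, p$id), sep = "\t"),
      paste(p$chrom, "t", "miRNA", p$m_start, p$m_end, ".", p$strand, ".",
            sprintf("ID=MIMAT%03d;Name=%s-mat;Derives_from=MI%03d",
                    i, p$id, i), sep = "\t"))
  }
  writeLines(lines, path)
  path
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

brute_force_mfe <- function(seq, params = loop_energy_params()) {
  structs <- enumerate_structures(seq)
  es <- vapply(structs, function(db) structure_energy(seq, db, params),
               numeric(1))
  list(mfe = min(es, 0), structures = structs, energies = es)
}
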