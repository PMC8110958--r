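#' Default pipeline configuration
#'
#' @param vcf,gff,hairpin_fasta required input paths.
#' @param utr_fasta,go_tsv optional inputs enabling the target-switch and
#'   enrichment stages for seed SNPs.
#' @param capture_bed optional targeted-region BED for the whole-target SNP
#'   density.
#' @param min_dp,min_gq ingest hard filters (exclusive thresholds; defaults
#'   5 and 30).
#' @param strand_convention substitution reporting strand (`"sense"` or
#'   `"vcf_ref"`).
#' @param engine fold engine (`"loop_energy"`, `"nussinov"`, `"external"`).
#' @param site_rule seed-match stringency (see [match_targets()]).
#' @param alpha enrichment significance threshold.
#' @param enrich_measure `"fdr"` (default) or `"p_value"`.
#' @param universe_rule `"annotated"` (genes with >= 1 GO annotation,
#'   default) or `"all_utr_genes"`.
#' @param out_dir optional output directory for report files.
#' @return list of class `mirsnp_config`.
#' @export
pipeline_config <- function(vcf, gff, hairpin_fasta,
                            utr_fasta = NULL, go_tsv = NULL,
                            capture_bed = NULL,
                            min_dp = 5, min_gq = 30,
                            strand_convention = "sense",
                            engine = "loop_energy",
                            site_rule = "any7plus",
                            alpha = 0.05,
                            enrich_measure = "fdr",
                            universe_rule = c("annotated", "all_utr_genes"),
                            out_dir = NULL) {
  universe_rule <- match.arg(universe_rule)
  cfg <- as.list(environment())
  required <- c(vcf = vcf, gff = gff, hairpin_fasta = hairpin_fasta)
  optional <- unlist(cfg[c("utr_fasta", "go_tsv", "capture_bed")])
  missing <- c(required[!file.exists(required)],
               if (length(optional)) optional[!file.exists(optional)])
  if (length(missing))
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = " = ", collapse = "; "))
  structure(cfg, class = "mirsnp_config")
}

#' Run the full miRNA-SNP analysis pipeline
#'
#' Orchestrates ingest (filtered VCF, miRNA GFF3, hairpin FASTA), SNP
#' compartment classification, substitution spectrum and compartment
#' summaries, population statistics, per-SNP hairpin folding
#' (reference vs SNP-altered, delta-delta-G), and -- when a 3'UTR FASTA and
#' GO annotation are configured -- target switching and comparative
#' enrichment for every seed SNP. Deterministic given identical inputs and
#' configuration. Counts are logged at every filter boundary.
#'
#' @param cfg a [pipeline_config()], or a path to a YAML file with the same
#'   fields.
#' @param quiet suppress progress messages.
#' @return list of class `mirsnp_report`; see the elements written by
#'   [write_report()] when `out_dir` is set.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    cfg <- do.call(pipeline_config, yaml::yaml.load_file(cfg))
  }
  stopifnot(inherits(cfg, "mirsnp_config"))
  say <- function(...) if (!quiet) message("[mirsnp] ", ...)

  stage <- "ingest"
  report <- tryCatch({
    vs <- read_vcf(cfg$vcf, min_dp = cfg$min_dp, min_gq = cfg$min_gq)
    say("ingest: ", nrow(vs$variants), " records pass DP > ", cfg$min_dp,
        " (", length(vs$samples), " samples)")
    ann <- read_mirna_gff(cfg$gff)
    ann <- attach_hairpins(ann, cfg$hairpin_fasta)
    say("ingest: ", nrow(ann$precursors), " precursors, ",
        nrow(ann$matures), " matures")

    stage <- "annotate"
    calls <- classify_variants(vs, ann,
                               strand_convention = cfg$strand_convention)
    in_pre_sites <- unique(calls[c("chrom", "pos")])
    # variants (any class) inside precursors, for the discovery funnel
    pre <- ann$precursors
    in_pre_any <- vapply(seq_len(nrow(vs$variants)), function(i)
      any(pre$chrom == vs$variants$chrom[i] &
          pre$start <= vs$variants$pos0[i] &
          vs$variants$pos0[i] < pre$end), logical(1))
    funnel <- list(n_pass_filters = nrow(vs$variants),
                   n_in_precursors = sum(in_pre_any),
                   n_snps_in_precursors = nrow(in_pre_sites))
    say("annotate: ", funnel$n_in_precursors, " variants in precursors, ",
        funnel$n_snps_in_precursors, " SNPs classified")
    comp <- compartment_summary(calls, ann = ann)
    spec_pre <- substitution_spectrum(calls, "precursor_all")
    spec_mat <- substitution_spectrum(calls, "mature_only")

    stage <- "stats"
    target_len <- if (!is.null(cfg$capture_bed)) {
      bed <- read_bed(cfg$capture_bed)
      sum(bed$end - bed$start)
    } else NA_real_
    pop_all <- snp_summary(vs, region_length_bp =
                             if (is.na(target_len)) NULL else target_len)
    snp_keys <- paste(vs$variants$chrom, vs$variants$pos)
    pre_keys <- paste(in_pre_sites$chrom, in_pre_sites$pos)
    vs_pre <- vs
    keep <- snp_keys %in% pre_keys & vs$variants$class == "SNP"
    vs_pre$variants <- vs$variants[keep, , drop = FALSE]
    vs_pre$gt <- vs$gt[keep, , drop = FALSE]
    premirna_len <- sum(pre$end - pre$start)
    pop_pre <- snp_summary(vs_pre, region_length_bp = premirna_len)
    say("stats: mean MAF ", round(pop_all$mean_maf, 3),
        ", mean het ", round(pop_all$mean_het, 2))

    stage <- "fold-impact"
    params <- loop_energy_params()
    ddg <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
      ddg_analysis(ann, calls[i, ], engine = cfg$engine, params = params)))
    ddg_sum <- if (!is.null(ddg)) cohort_ddg_summary(ddg) else NULL
    if (!is.null(ddg_sum))
      say("fold-impact: ", ddg_sum$n_nonzero, " SNPs with nonzero ddG, ",
          ddg_sum$n_structure_changed, " structure changes")

    stage <- "target-switch"
    switches <- list()
    if (!is.null(cfg$utr_fasta) && !is.null(cfg$go_tsv)) {
      utrs <- read_fasta(cfg$utr_fasta)
      go <- read_go_annotation(cfg$go_tsv)
      universe <- if (cfg$universe_rule == "annotated")
        intersect(names(utrs), unique(go$gene)) else names(utrs)
      seed_calls <- calls[calls$compartment == "seed", , drop = FALSE]
      for (i in seq_len(nrow(seed_calls))) {
        sc <- seed_calls[i, ]
        ref_seed <- extract_seed(ann, sc$mature_id)
        alt_seed <- extract_seed(ann, sc$mature_id, snp = sc)
        t_ref <- match_targets(ref_seed, utrs, site_rule = cfg$site_rule)
        t_alt <- match_targets(alt_seed, utrs, site_rule = cfg$site_rule)
        sw <- switch_analysis(t_ref, t_alt, mirna_id = sc$mature_id)
        e_ref <- hypergeom_enrich(intersect(t_ref, universe), go,
                                  universe = universe)
        e_alt <- hypergeom_enrich(intersect(t_alt, universe), go,
                                  universe = universe)
        cmp <- compare_enrichment(e_ref, e_alt, alpha = cfg$alpha,
                                  measure = cfg$enrich_measure)
        say("target-switch ", sc$mature_id, ": ",
            paste(names(sw$counts), sw$counts, sep = "=", collapse = " "))
        switches[[sc$mature_id]] <- list(
          seed_ref = ref_seed$seed7, seed_alt = alt_seed$seed7,
          switch = sw, enrich_ref = e_ref, enrich_alt = e_alt,
          comparison = cmp)
      }
    }

    structure(list(
      funnel = funnel, compartments = comp,
      spectrum_precursor = spec_pre, spectrum_mature = spec_mat,
      popgen_all = pop_all, popgen_premirna = pop_pre,
      calls = calls, ddg = ddg, ddg_summary = ddg_sum,
      switches = switches,
      config = unclass(cfg), version = as.character(utils::packageVersion("mirsnp"))),
      class = "mirsnp_report")
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  if (!is.null(cfg$out_dir)) {
    tables <- list(calls = report$calls, ddg = report$ddg)
    for (nm in names(report$switches)) {
      tables[[paste0("enrich_ref_", nm)]] <- report$switches[[nm]]$enrich_ref
      tables[[paste0("enrich_alt_", nm)]] <- report$switches[[nm]]$enrich_alt
      tables[[paste0("enrich_cmp_", nm)]] <- report$switches[[nm]]$comparison
    }
    tables <- c(tables, report_summary(report))
    write_report(tables, cfg$out_dir)
  }
  report
}

report_summary <- function(report) {
  sw <- lapply(report$switches, function(s)
    c(as.list(s$switch$counts),
      list(seed_ref = s$seed_ref, seed_alt = s$seed_alt,
           n_sig_ref = sum(s$comparison$status != "alt_only"),
           n_sig_alt = sum(s$comparison$status != "ref_only"))))
  list(funnel = report$funnel,
       compartments = report$compartments,
       spectrum_precursor = report$spectrum_precursor[
         c("n", "n_transitions", "ts_percent", "tv_percent")],
       spectrum_mature = report$spectrum_mature[
         c("n", "n_transitions", "ts_percent", "tv_percent")],
       popgen_all = report$popgen_all[
         c("n_snps", "mean_maf", "sd_maf", "mean_het", "distances",
           "density_per_kb")],
       popgen_premirna = report$popgen_premirna[
         c("n_snps", "mean_maf", "sd_maf", "mean_het", "distances",
           "density_per_kb")],
       ddg = report$ddg_summary,
       switches = sw, config = report$config, version = report$version)
}

#' @exportS3Method base::print
print.mirsnp_report <- function(x, ...) {
  cat("mirsnp pipeline report\n")
  cat("  variants passing filters:", x$funnel$n_pass_filters, "\n")
  cat("  variants in precursors:  ", x$funnel$n_in_precursors, "\n")
  cat("  SNPs in precursors:      ", x$funnel$n_snps_in_precursors,
      sprintf("(in %d unique precursors, %.1f%%)",
              x$compartments$n_unique_precursors,
              x$compartments$unique_precursor_percent), "\n")
  cat("  compartments: ",
      paste(names(x$compartments$counts), x$compartments$counts,
            sep = "=", collapse = " "),
      sprintf(" (%.1f%% / %.1f%% / %.1f%%)\n", x$compartments$percent[1],
              x$compartments$percent[2], x$compartments$percent[3]))
  cat("  transitions:", x$spectrum_precursor$ts_percent,
      "% (precursor scope),", x$spectrum_mature$ts_percent,
      "% (mature scope)\n")
  cat(sprintf("  mean MAF %.3f (+/- %.3f), mean het %.2f\n",
              x$popgen_all$mean_maf, x$popgen_all$sd_maf,
              x$popgen_all$mean_het))
  if (!is.null(x$ddg_summary))
    cat(sprintf("  ddG: %d nonzero (%d up, %d down), mean |ddG| %.2f, %d structure changes\n",
                x$ddg_summary$n_nonzero, x$ddg_summary$n_increase,
                x$ddg_summary$n_decrease, x$ddg_summary$mean_abs_ddg,
                x$ddg_summary$n_structure_changed))
  for (nm in names(x$switches)) {
    s <- x$switches[[nm]]
    cat("  ", nm, ": ", paste(names(s$switch$counts), s$switch$counts,
                              sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
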