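#' Configuration for the synthetic miRNA-SNP cohort generator
#'
#' Defaults emulate the study design the pipeline is built for: 23 diploid
#' animals genotyped over 381 hairpin precursors, 73 planted SNPs in 50
#' distinct precursors split 2 (seed) / 12 (mature beyond seed) / 59
#' (precursor beyond mature), a transition-rich substitution spectrum
#' (10/14 transitions in mature sequences, 50/59 elsewhere), 8 indel records
#' and a handful of low-depth decoys so the ingest filters are exercised,
#' plus 3'UTRs with planted seed-match sites and a GO map with planted
#' enrichment.
#'
#' @param seed RNG seed (integer).
#' @param n_precursors number of hairpin precursors.
#' @param frac_minus_strand fraction of precursors annotated on the minus
#'   strand.
#' @param stem_len_range,loop_len_range inclusive ranges (bp) for the stem
#'   and terminal loop of each constructed hairpin.
#' @param n_seed_snps,n_mature_snps,n_premirna_snps planted SNPs per
#'   compartment (seed / mature beyond seed / precursor beyond mature).
#' @param n_snp_precursors number of distinct precursors carrying SNPs.
#' @param n_transitions_mature transitions among the seed + mature SNPs.
#' @param n_transitions_premirna transitions among the
#'   precursor-beyond-mature SNPs.
#' @param n_stem_disrupt,n_loop_neutral planted stability classes among the
#'   precursor-beyond-mature SNPs: mid-stem Watson-Crick pair broken to a
#'   mismatch (expected destabilising, structure change) vs terminal-loop
#'   substitution (expected neutral under the loop-energy model).
#' @param n_indels,n_lowdp indel records and low-depth (DP <= 5) decoy SNPs
#'   planted inside precursors.
#' @param n_background_snps SNPs planted in capture flanks outside
#'   precursors.
#' @param n_samples diploid samples.
#' @param maf_range uniform range for the true alt-allele frequency.
#' @param low_gq_rate per-genotype probability of a failing genotype quality
#'   (GQ <= 30).
#' @param flank_bp capture-region flank around each precursor.
#' @param n_chrom chromosomes used for the layout.
#' @param n_utr_genes,utr_len 3'UTR universe size and length.
#' @param n_common_sites,n_lost_sites,n_gained_sites per seed-SNP miRNA:
#'   genes given sites for both seeds / the reference seed only / the
#'   altered seed only.
#' @param n_go_terms background GO terms.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_precursors = 381L,
                       frac_minus_strand = 0.5,
                       stem_len_range = c(26L, 41L),
                       loop_len_range = c(8L, 15L),
                       n_seed_snps = 2L,
                       n_mature_snps = 12L,
                       n_premirna_snps = 59L,
                       n_snp_precursors = 50L,
                       n_transitions_mature = 10L,
                       n_transitions_premirna = 50L,
                       n_stem_disrupt = 10L,
                       n_loop_neutral = 6L,
                       n_indels = 8L,
                       n_lowdp = 4L,
                       n_background_snps = 200L,
                       n_samples = 23L,
                       maf_range = c(0.05, 0.5),
                       low_gq_rate = 0.02,
                       flank_bp = 80L,
                       n_chrom = 19L,
                       n_utr_genes = 500L,
                       utr_len = 500L,
                       n_common_sites = 20L,
                       n_lost_sites = 40L,
                       n_gained_sites = 25L,
                       n_go_terms = 30L) {
  cfg <- as.list(environment())
  n_snps <- cfg$n_seed_snps + cfg$n_mature_snps + cfg$n_premirna_snps
  if (cfg$n_snp_precursors > n_snps)
    stop("more SNP precursors than SNPs")
  if (cfg$n_snp_precursors > cfg$n_precursors)
    stop("more SNP precursors than precursors")
  if (cfg$n_seed_snps > 6 * cfg$n_snp_precursors)
    stop("infeasible placement: more seed SNPs than seed positions")
  if (cfg$n_stem_disrupt + cfg$n_loop_neutral > cfg$n_premirna_snps)
    stop("stability classes exceed precursor-beyond-mature SNP count")
  if (cfg$n_transitions_premirna > cfg$n_premirna_snps - cfg$n_loop_neutral)
    stop("loop-neutral SNPs are transversions; transition quota infeasible")
  structure(cfg, class = "sim_config")
}

RNA_TRANSITION <- c(A = "G", G = "A", C = "U", U = "C")
RNA_TRANSVERSIONS <- list(A = c("C", "U"), G = c("C", "U"),
                          C = c("A", "G"), U = c("A", "G"))

#' Construct a stem-loop RNA sequence
#'
#' Builds `stem + loop + reverse-complement(stem)` with a configurable
#' fraction of wobble (G.U) pairs replacing Watson-Crick pairs in the stem,
#' and a loop drawn from A/C so the loop cannot pair internally. Under the
#' loop-energy engine the minimum-free-energy structure of such a sequence
#' recovers the designed stem.
#'
#' @param stem_len stem length in pairs (>= 5).
#' @param loop_len terminal loop length (>= 3).
#' @param wc_frac minimum Watson-Crick fraction of the stem (default 0.9;
#'   the remainder becomes G.U wobbles where the stem sequence allows).
#' @return RNA string of length `2 * stem_len + loop_len`. Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
make_hairpin <- function(stem_len, loop_len, wc_frac = 0.9) {
  stopifnot(stem_len >= 5, loop_len >= 3)
  top <- sample(RNA_BASES, stem_len, replace = TRUE)
  bottom <- rev(chartr("ACGU", "UGCA", top))
  # convert up to (1 - wc_frac) of the stem to G.U wobbles
  n_wob <- floor((1 - wc_frac) * stem_len)
  cand <- which(top %in% c("G", "U"))
  wob <- if (n_wob > 0 && length(cand)) sample(cand, min(n_wob, length(cand)))
         else integer(0)
  for (t in wob) {
    bi <- stem_len - t + 1  # bottom index pairing top position t
    bottom[bi] <- if (top[t] == "G") "U" else "G"
  }
  loop <- sample(c("A", "C"), loop_len, replace = TRUE)
  paste(c(top, loop, bottom), collapse = "")
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

hw_genotypes <- function(n, p) {
  repeat {
    g <- stats::rbinom(n, 2, p)
    if (sum(g) > 0) return(g)  # a called variant carries >= 1 alt allele
  }
}

## site patterns used by the generator's own bookkeeping (plain substring
## checks, kept separate from match_targets so the recovery tests exercise
## the pipeline's own pattern construction)
sim_site_patterns <- function(seed7) {
  core7 <- revcomp(rna_to_dna(seed7), "dna")
  core6 <- revcomp(rna_to_dna(substr(seed7, 1, 6)), "dna")
  c(core7, paste0(core6, "A"), paste0(core7, "A"))
}
sim_has_site <- function(utr, seed7)
  any(vapply(sim_site_patterns(seed7), grepl, logical(1), x = utr, fixed = TRUE))
sim_has_core6 <- function(utr, seed7)
  grepl(revcomp(rna_to_dna(substr(seed7, 1, 6)), "dna"), utr, fixed = TRUE)

#' Generate a fully self-contained synthetic cohort
#'
#' Emits every input the pipeline consumes -- genome FASTA, miRBase-dialect
#' GFF3, VCF with per-sample genotypes (DP/GQ populated, including records
#' planted to fail the ingest filters), hairpin FASTA, capture BED, 3'UTR
#' FASTA and a gene-to-GO TSV -- together with machine-readable truth tables
#' recording every planted SNP's compartment, sense substitution, true
#' allele frequency and stability class, and every planted target site and
#' enriched term. Byte-identical outputs for identical configurations.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return list with `paths` (named file paths), `truth` (list of
#'   data.frames: `snps`, `targets`, `go`), and `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = tempfile("mirsnp_sim_")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  chroms <- c(paste0("chr", seq_len(cfg$n_chrom - 1)), "chrX")

  ## ---- precursors -------------------------------------------------------
  n <- cfg$n_precursors
  pre <- data.frame(
    precursor_id = sprintf("sim-mir-%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = ifelse(stats::runif(n) < cfg$frac_minus_strand, "-", "+"),
    stem_len = sample(cfg$stem_len_range[1]:cfg$stem_len_range[2], n, TRUE),
    loop_len = sample(cfg$loop_len_range[1]:cfg$loop_len_range[2], n, TRUE),
    stringsAsFactors = FALSE)
  pre$hairpin <- vapply(seq_len(n), function(i)
    make_hairpin(pre$stem_len[i], pre$loop_len[i]), character(1))
  pre$len <- nchar(pre$hairpin)
  # mature: 22 nt on one arm, small offset from the hairpin end
  pre$arm <- sample(c("5p", "3p"), n, replace = TRUE)
  off5 <- sample(0:2, n, replace = TRUE)
  pre$m_off <- ifelse(pre$arm == "5p", off5, pre$len - 22L - off5)
  pre$mature_id <- paste0(pre$precursor_id, "-", pre$arm)

  ## ---- genome layout (0-based starts) -----------------------------------
  pre$start <- NA_integer_
  chrom_seq <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    idx <- which(pre$chrom == ch)
    cursor <- 0L
    parts <- character(0)
    for (i in idx) {
      gap <- sample(170:260, 1)
      parts <- c(parts, rand_dna(gap))
      cursor <- cursor + gap
      pre$start[i] <- cursor
      gseq <- rna_to_dna(pre$hairpin[i])
      if (pre$strand[i] == "-") gseq <- revcomp(gseq, "dna")
      parts <- c(parts, gseq)
      cursor <- cursor + pre$len[i]
    }
    parts <- c(parts, rand_dna(200))
    chrom_seq[[ch]] <- paste(parts, collapse = "")
  }
  pre$end <- pre$start + pre$len

  ## ---- SNP plan ---------------------------------------------------------
  chosen <- sample(pre$precursor_id, cfg$n_snp_precursors)
  slots <- data.frame(precursor_id = chosen, stringsAsFactors = FALSE)
  slots$compartment <- "precursor_nonmature"
  slots$compartment[seq_len(cfg$n_seed_snps)] <- "seed"
  slots$compartment[cfg$n_seed_snps + seq_len(cfg$n_mature_snps)] <-
    "mature_nonseed"
  n_extra <- cfg$n_seed_snps + cfg$n_mature_snps + cfg$n_premirna_snps -
    cfg$n_snp_precursors
  if (n_extra > 0)
    slots <- rbind(slots, data.frame(
      precursor_id = sample(chosen, n_extra),
      compartment = "precursor_nonmature", stringsAsFactors = FALSE))

  pm <- which(slots$compartment == "precursor_nonmature")
  slots$ddg_class <- "other"
  slots$ddg_class[pm[seq_len(cfg$n_stem_disrupt)]] <- "stem_disrupt"
  slots$ddg_class[pm[cfg$n_stem_disrupt + seq_len(cfg$n_loop_neutral)]] <-
    "loop_neutral"

  # transition quotas: seed SNPs are transitions; stem disruptions are G>A
  # transitions; loop-neutral SNPs are A<->C transversions by construction
  slots$transition <- NA
  mat_idx <- which(slots$compartment %in% c("seed", "mature_nonseed"))
  slots$transition[slots$compartment == "seed"] <- TRUE
  ns_idx <- which(slots$compartment == "mature_nonseed")
  need_m <- cfg$n_transitions_mature - cfg$n_seed_snps
  slots$transition[ns_idx] <- seq_along(ns_idx) %in%
    sample(seq_along(ns_idx), need_m)
  slots$transition[slots$ddg_class == "stem_disrupt"] <- TRUE
  slots$transition[slots$ddg_class == "loop_neutral"] <- FALSE
  other_idx <- which(slots$compartment == "precursor_nonmature" &
                     slots$ddg_class == "other")
  need_p <- cfg$n_transitions_premirna - cfg$n_stem_disrupt
  slots$transition[other_idx] <- seq_along(other_idx) %in%
    sample(seq_along(other_idx), need_p)

  ## ---- place each planted SNP in hairpin coordinates --------------------
  used <- stats::setNames(vector("list", n), pre$precursor_id)
  base_at <- function(i, off) substring(pre$hairpin[i], off + 1, off + 1)
  snp_rows <- list()
  for (s in seq_len(nrow(slots))) {
    i <- match(slots$precursor_id[s], pre$precursor_id)
    L <- pre$len[i]; sl <- pre$stem_len[i]; ll <- pre$loop_len[i]
    m0 <- pre$m_off[i]
    mature <- m0:(m0 + 21)
    comp <- slots$compartment[s]
    repeat {
      if (comp == "seed") {
        mp <- sample(2:7, 1)  # interior seed positions keep ref/alt
                              # site cores distinct for target planting
        off <- m0 + mp - 1
      } else if (comp == "mature_nonseed") {
        mp <- sample(c(1, 9:22), 1)
        off <- m0 + mp - 1
      } else if (slots$ddg_class[s] == "loop_neutral") {
        off <- sl + sample(seq_len(ll), 1) - 1
      } else if (slots$ddg_class[s] == "stem_disrupt") {
        # a G whose designed partner is a Watson-Crick C, >= 3 pairs from
        # both helix ends, on the arm opposite the mature
        arm_off <- if (pre$arm[i] == "5p") (sl + ll):(L - 1) else 0:(sl - 1)
        arm_idx <- if (pre$arm[i] == "5p") arm_off - sl - ll else arm_off
        ok <- arm_off[base_at(i, arm_off) == "G" &
                      base_at(i, L - 1 - arm_off) == "C" &
                      pmin(arm_idx, sl - 1 - arm_idx) >= 3]
        ok <- setdiff(ok, mature)
        if (!length(ok)) stop("no stem-disruption position in ",
                              pre$precursor_id[i])
        off <- sample(rep(ok, 2), 1)
      } else {
        off <- sample(setdiff(0:(L - 1), mature), 1)
      }
      if (!(off %in% used[[i]])) break
    }
    used[[i]] <- c(used[[i]], off)
    ref <- base_at(i, off)
    alt <- if (slots$ddg_class[s] == "stem_disrupt") "A"  # G>A mismatch
      else if (slots$ddg_class[s] == "loop_neutral") {
        if (ref == "A") "C" else "A"
      } else if (isTRUE(slots$transition[s])) RNA_TRANSITION[[ref]]
      else sample(rep(RNA_TRANSVERSIONS[[ref]], 2), 1)
    snp_rows[[s]] <- data.frame(
      precursor_id = pre$precursor_id[i],
      mature_id = if (comp == "precursor_nonmature") NA_character_
                  else pre$mature_id[i],
      compartment = comp,
      mature_position = if (comp == "precursor_nonmature") NA_integer_
                        else as.integer(mp),
      hairpin_offset = as.integer(off),
      sense_ref = ref, sense_alt = alt,
      is_transition = unname(is_transition(ref, alt)),
      ddg_class = if (comp == "precursor_nonmature") slots$ddg_class[s]
                  else "other",
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)

  ## ---- genome/VCF coordinates and genotypes -----------------------------
  pi <- match(snps$precursor_id, pre$precursor_id)
  plus <- pre$strand[pi] == "+"
  snps$chrom <- pre$chrom[pi]
  snps$pos0 <- ifelse(plus, pre$start[pi] + snps$hairpin_offset,
                      pre$start[pi] + pre$len[pi] - 1L - snps$hairpin_offset)
  snps$pos <- snps$pos0 + 1L
  snps$strand <- pre$strand[pi]
  snps$vcf_ref <- ifelse(plus, rna_to_dna(snps$sense_ref),
                         complement_base(rna_to_dna(snps$sense_ref)))
  snps$vcf_alt <- ifelse(plus, rna_to_dna(snps$sense_alt),
                         complement_base(rna_to_dna(snps$sense_alt)))
  snps$true_af <- stats::runif(nrow(snps), cfg$maf_range[1], cfg$maf_range[2])

  ns <- cfg$n_samples
  sample_ids <- sprintf("pig%02d", seq_len(ns))
  gt_mat <- t(vapply(snps$true_af, function(p) hw_genotypes(ns, p),
                     integer(ns)))

  genome_base <- function(ch, pos0, len = 1)
    substr(chrom_seq[[ch]], pos0 + 1, pos0 + len)

  vcf_records <- list()
  add_record <- function(chrom, pos0, ref, alt, dp, gts, gqs) {
    vcf_records[[length(vcf_records) + 1]] <<- list(
      chrom = chrom, pos = pos0 + 1L, ref = ref, alt = alt, dp = dp,
      gts = gts, gqs = gqs)
  }
  draw_gq <- function() {
    gq <- sample(40:99, ns, replace = TRUE)
    low <- stats::runif(ns) < cfg$low_gq_rate
    gq[low] <- sample(5:30, sum(low), replace = TRUE)
    gq
  }
  gt_str <- function(g) c("0/0", "0/1", "1/1")[g + 1]

  for (s in seq_len(nrow(snps)))
    add_record(snps$chrom[s], snps$pos0[s], snps$vcf_ref[s], snps$vcf_alt[s],
               dp = sample(20:90, 1), gts = gt_str(gt_mat[s, ]),
               gqs = draw_gq())

  ## indels inside precursors (pass filters; excluded by the SNP restriction)
  taken <- split(snps$pos0, snps$chrom)
  pick_free_pos <- function(lo, hi, ch) {
    repeat {
      p <- sample(lo:hi, 1)
      if (!(p %in% taken[[ch]])) {
        taken[[ch]] <<- c(taken[[ch]], p)
        return(p)
      }
    }
  }
  ind_pre <- sample(seq_len(n), cfg$n_indels)
  for (i in ind_pre) {
    p0 <- pick_free_pos(pre$start[i], pre$end[i] - 2L, pre$chrom[i])
    ref1 <- genome_base(pre$chrom[i], p0)
    if (stats::runif(1) < 0.5) {   # deletion
      ref <- genome_base(pre$chrom[i], p0, 2); alt <- ref1
    } else {                        # insertion
      ref <- ref1; alt <- paste0(ref1, sample(DNA_BASES, 1))
    }
    g <- hw_genotypes(ns, stats::runif(1, cfg$maf_range[1], cfg$maf_range[2]))
    add_record(pre$chrom[i], p0, ref, alt, dp = sample(20:90, 1),
               gts = gt_str(g), gqs = draw_gq())
  }

  ## low-depth decoy SNPs inside precursors (removed by DP > min_dp)
  for (i in sample(seq_len(n), cfg$n_lowdp)) {
    p0 <- pick_free_pos(pre$start[i], pre$end[i] - 1L, pre$chrom[i])
    ref <- genome_base(pre$chrom[i], p0)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
    g <- hw_genotypes(ns, stats::runif(1, cfg$maf_range[1], cfg$maf_range[2]))
    add_record(pre$chrom[i], p0, ref, alt, dp = sample(1:5, 1),
               gts = gt_str(g), gqs = draw_gq())
  }

  ## background SNPs in capture flanks, outside any precursor
  for (b in seq_len(cfg$n_background_snps)) {
    i <- sample(seq_len(n), 1)
    side <- sample(c("left", "right"), 1)
    lo <- if (side == "left") max(0, pre$start[i] - cfg$flank_bp)
          else pre$end[i]
    hi <- if (side == "left") pre$start[i] - 1L
          else pre$end[i] + cfg$flank_bp - 1L
    if (hi < lo) next
    p0 <- pick_free_pos(lo, hi, pre$chrom[i])
    ref <- genome_base(pre$chrom[i], p0)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
    g <- hw_genotypes(ns, stats::runif(1, cfg$maf_range[1], cfg$maf_range[2]))
    add_record(pre$chrom[i], p0, ref, alt, dp = sample(20:90, 1),
               gts = gt_str(g), gqs = draw_gq())
  }

  ## ---- seed-SNP target planting -----------------------------------------
  seed_snps <- snps[snps$compartment == "seed", , drop = FALSE]
  seed_specs <- lapply(seq_len(nrow(seed_snps)), function(s) {
    i <- match(seed_snps$precursor_id[s], pre$precursor_id)
    mseq <- substr(pre$hairpin[i], pre$m_off[i] + 1, pre$m_off[i] + 22)
    ref7 <- substr(mseq, 2, 8)
    alt7 <- ref7
    substr(alt7, seed_snps$mature_position[s] - 1,
           seed_snps$mature_position[s] - 1) <- seed_snps$sense_alt[s]
    list(mirna_id = seed_snps$mature_id[s], ref = ref7, alt = alt7)
  })
  all_seed7 <- unlist(lapply(seed_specs, function(x) c(x$ref, x$alt)))

  genes <- sprintf("g%04d", seq_len(cfg$n_utr_genes))
  per_mirna <- cfg$n_common_sites + cfg$n_lost_sites + cfg$n_gained_sites
  if (per_mirna * length(seed_specs) > cfg$n_utr_genes)
    stop("not enough UTR genes for the planted target sets")
  pool <- sample(genes)
  target_truth <- list()
  plant <- stats::setNames(vector("list", length(genes)), genes)
  for (m in seq_along(seed_specs)) {
    sp <- seed_specs[[m]]
    take <- pool[seq_len(per_mirna)]; pool <- pool[-seq_len(per_mirna)]
    sets <- rep(c("common", "lost", "gained"),
                c(cfg$n_common_sites, cfg$n_lost_sites, cfg$n_gained_sites))
    for (g in seq_along(take)) {
      site_seeds <- switch(sets[g], common = c(sp$ref, sp$alt),
                           lost = sp$ref, gained = sp$alt)
      plant[[take[g]]] <- c(plant[[take[g]]],
                            lapply(site_seeds, function(s7)
                              paste0(revcomp(rna_to_dna(s7), "dna"), "A")))
      target_truth[[length(target_truth) + 1]] <- data.frame(
        mirna_id = sp$mirna_id, gene = take[g], set = sets[g],
        stringsAsFactors = FALSE)
    }
  }
  target_truth <- do.call(rbind, target_truth)

  # which seed (columns: ref1, alt1, ref2, alt2, ...) each gene must match
  design <- matrix(FALSE, length(genes), length(all_seed7),
                   dimnames = list(genes, NULL))
  for (m in seq_along(seed_specs)) {
    tt <- target_truth[target_truth$mirna_id == seed_specs[[m]]$mirna_id, ]
    design[tt$gene[tt$set %in% c("common", "lost")], 2 * m - 1] <- TRUE
    design[tt$gene[tt$set %in% c("common", "gained")], 2 * m] <- TRUE
  }
  # a planted site string must never itself satisfy an unintended seed;
  # matches that span into the random context are repaired by regeneration
  for (g in genes) {
    for (st in plant[[g]] %||% list()) {
      hits <- vapply(all_seed7, sim_has_site, logical(1), utr = st)
      if (any(hits & !design[g, ]))
        stop("site planting infeasible: seed cores collide for gene ", g)
    }
  }
  utrs <- character(length(genes)); names(utrs) <- genes
  for (g in genes) {
    sites <- plant[[g]]
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > 200) stop("could not generate a clean UTR for ", g)
      u <- rand_dna(cfg$utr_len)
      if (length(sites)) {
        # spread planted 8mer sites across the UTR, non-overlapping
        span <- floor(cfg$utr_len / length(sites))
        for (k in seq_along(sites)) {
          at <- (k - 1) * span + sample(seq_len(span - 10), 1)
          substr(u, at, at + 7) <- sites[[k]]
        }
      }
      got <- vapply(all_seed7, sim_has_site, logical(1), utr = u)
      if (all(got == design[g, ])) break
    }
    utrs[[g]] <- u
  }

  ## ---- GO annotation with planted enrichment ----------------------------
  go_rows <- list()
  add_go <- function(term, gs)
    go_rows[[length(go_rows) + 1]] <<- data.frame(gene = gs, term = term,
                                                  stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_go_terms))
    add_go(sprintf("GO:SIM%04d", t),
           sample(genes, sample(10:40, 1)))
  sp1 <- seed_specs[[1]]
  tt1 <- target_truth[target_truth$mirna_id == sp1$mirna_id, ]
  ref_targets1 <- tt1$gene[tt1$set %in% c("common", "lost")]
  gained1 <- tt1$gene[tt1$set == "gained"]
  nontarget1 <- setdiff(genes, tt1$gene)
  # planted effects scale with the target-set sizes so small cohorts stay
  # strongly enriched
  n_ref_hit <- max(3, min(15, floor(0.75 * length(ref_targets1))))
  n_alt_hit <- max(3, min(12, floor(0.8 * length(gained1))))
  add_go("GO:SIMREF1", c(sample(ref_targets1, n_ref_hit),
                         sample(nontarget1, max(2, ceiling(n_ref_hit / 3)))))
  add_go("GO:SIMALT1", c(sample(gained1, n_alt_hit),
                         sample(nontarget1, max(2, ceiling(n_alt_hit / 1.5)))))
  # every gene annotated at least once so the annotated universe is complete
  ann_genes <- unique(unlist(lapply(go_rows, `[[`, "gene")))
  left <- setdiff(genes, ann_genes)
  if (length(left))
    for (g in left) add_go(sprintf("GO:SIM%04d", sample(cfg$n_go_terms, 1)), g)
  go_tab <- do.call(rbind, go_rows)
  go_truth <- data.frame(
    term = c("GO:SIMREF1", "GO:SIMALT1"),
    mirna_id = sp1$mirna_id,
    expected = c("ref_enriched", "alt_only"),
    stringsAsFactors = FALSE)

  ## ---- write files ------------------------------------------------------
  paths <- list(
    genome_fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "mirna.gff3"),
    hairpin_fasta = file.path(dir, "hairpin.fa"),
    vcf = file.path(dir, "variants.vcf"),
    capture_bed = file.path(dir, "capture.bed"),
    utr_fasta = file.path(dir, "utr.fa"),
    go_tsv = file.path(dir, "go_annotation.tsv"),
    truth_snps = file.path(dir, "truth_snps.tsv"),
    truth_targets = file.path(dir, "truth_targets.tsv"),
    truth_go = file.path(dir, "truth_go.tsv"))

  write_fa <- function(seqs, path) {
    con <- file(path, "w")
    for (nm in names(seqs)) {
      cat(">", nm, "\n", sep = "", file = con)
      s <- seqs[[nm]]
      for (k in seq(1, nchar(s), 70))
        cat(substr(s, k, min(k + 69, nchar(s))), "\n", sep = "", file = con)
    }
    close(con)
  }
  write_fa(vapply(chrom_seq, identity, character(1)), paths$genome_fasta)
  write_fa(stats::setNames(pre$hairpin, pre$precursor_id), paths$hairpin_fasta)
  write_fa(utrs, paths$utr_fasta)

  gff <- c("##gff-version 3")
  for (i in seq_len(n)) {
    attr_p <- sprintf("ID=MI_SIM%04d;Name=%s", i, pre$precursor_id[i])
    gff <- c(gff, paste(pre$chrom[i], "sim", "miRNA_primary_transcript",
                        pre$start[i] + 1L, pre$end[i], ".", pre$strand[i], ".",
                        attr_p, sep = "\t"))
    if (pre$strand[i] == "+") {
      ms <- pre$start[i] + pre$m_off[i]; me <- ms + 22L
    } else {
      me <- pre$end[i] - pre$m_off[i]; ms <- me - 22L
    }
    attr_m <- sprintf("ID=MIMAT_SIM%04d;Name=%s;Derives_from=MI_SIM%04d",
                      i, pre$mature_id[i], i)
    gff <- c(gff, paste(pre$chrom[i], "sim", "miRNA", ms + 1L, me, ".",
                        pre$strand[i], ".", attr_m, sep = "\t"))
  }
  writeLines(gff, paths$gff)

  bed <- data.frame(chrom = pre$chrom,
                    start = pmax(0L, pre$start - cfg$flank_bp),
                    end = pre$end + cfg$flank_bp)
  chrom_rank <- match(bed$chrom, chroms)
  bed <- bed[order(chrom_rank, bed$start), ]
  utils::write.table(bed, paths$capture_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  rec_chrom <- vapply(vcf_records, `[[`, character(1), "chrom")
  rec_pos <- vapply(vcf_records, `[[`, integer(1), "pos")
  ord <- order(match(rec_chrom, chroms), rec_pos)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=mirsnp_simulate",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  for (r in vcf_records[ord]) {
    gt_field <- paste(r$gts, r$gqs, sep = ":")
    vcf_lines <- c(vcf_lines, paste(
      c(r$chrom, r$pos, ".", r$ref, r$alt, "100", "PASS",
        paste0("DP=", r$dp), "GT:GQ", gt_field), collapse = "\t"))
  }
  writeLines(vcf_lines, paths$vcf)

  truth_snps <- snps[c("chrom", "pos", "strand", "precursor_id", "mature_id",
                       "compartment", "mature_position", "hairpin_offset",
                       "vcf_ref", "vcf_alt", "sense_ref", "sense_alt",
                       "is_transition", "ddg_class", "true_af")]
  utils::write.table(truth_snps, paths$truth_snps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(target_truth, paths$truth_targets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(go_truth, paths$truth_go, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(go_tab, paths$go_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = paths, truth = list(snps = truth_snps, targets = target_truth,
                                   go = go_truth),
       cfg = cfg, dir = dir)
}
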