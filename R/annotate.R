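#' Place one SNP into the miRNA compartment hierarchy
#'
#' Classifies a single SNP against a single precursor annotation. Compartment
#' priority is seed > mature (beyond seed) > precursor (beyond mature). The
#' seed is mature positions 2-8 inclusive, 1-based from the mature 5' end;
#' on the minus strand position 1 is the genomically rightmost mature base.
#' Sense alleles are the VCF alleles reverse-complemented on minus-strand
#' precursors. A SNP falling in two overlapping matures of the same
#' precursor yields one call per mature, flagged `ambiguous`.
#'
#' @param variant one row of a `variant_set` variants data.frame
#'   (`class` must be `"SNP"`).
#' @param ann a `mirna_annotation`.
#' @param precursor_id classify against this precursor only (default: every
#'   precursor containing the SNP).
#' @return data.frame of compartment calls (zero rows if the SNP lies in no
#'   precursor): `chrom`, `pos`, `pos0`, `precursor_id`, `compartment`,
#'   `mature_id`, `mature_position`, `hairpin_offset`, `vcf_ref`, `vcf_alt`,
#'   `sense_ref`, `sense_alt`, `substitution`, `is_transition`, `ambiguous`.
#' @export
classify_snp <- function(variant, ann, precursor_id = NULL) {
  stopifnot(identical(variant$class, "SNP"))
  pos0 <- variant$pos0
  pre <- ann$precursors
  hit <- pre[pre$chrom == variant$chrom & pre$start <= pos0 & pos0 < pre$end, ]
  if (!is.null(precursor_id)) hit <- hit[hit$precursor_id %in% precursor_id, ]
  if (nrow(hit) == 0) return(empty_calls())
  out <- lapply(seq_len(nrow(hit)), function(i) {
    p <- hit[i, ]
    strand <- p$strand
    hairpin_offset <- if (strand == "+") pos0 - p$start else p$end - 1L - pos0
    sense_ref <- if (strand == "+") variant$ref else complement_base(variant$ref)
    sense_alt <- if (strand == "+") variant$alt else complement_base(variant$alt)
    mats <- ann$matures[ann$matures$precursor_id == p$precursor_id &
                        ann$matures$start <= pos0 & pos0 < ann$matures$end, ]
    base <- data.frame(
      chrom = variant$chrom, pos = variant$pos, pos0 = pos0,
      precursor_id = p$precursor_id, compartment = "precursor_nonmature",
      mature_id = NA_character_, mature_position = NA_integer_,
      hairpin_offset = hairpin_offset,
      vcf_ref = variant$ref, vcf_alt = variant$alt,
      sense_ref = sense_ref, sense_alt = sense_alt,
      substitution = paste0(sense_ref, ">", rna_to_dna(sense_alt)),
      is_transition = is_transition(sense_ref, sense_alt),
      ambiguous = FALSE, stringsAsFactors = FALSE)
    if (nrow(mats) == 0) return(base)
    calls <- do.call(rbind, lapply(seq_len(nrow(mats)), function(m) {
      mt <- mats[m, ]
      mature_position <- if (strand == "+") pos0 - mt$start + 1L else mt$end - pos0
      b <- base
      b$mature_id <- mt$mature_id
      b$mature_position <- as.integer(mature_position)
      b$compartment <- if (mature_position >= 2 && mature_position <= 8)
        "seed" else "mature_nonseed"
      b
    }))
    calls$ambiguous <- nrow(calls) > 1
    calls
  })
  do.call(rbind, out)
}

empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), pos0 = integer(0),
             precursor_id = character(0), compartment = character(0),
             mature_id = character(0), mature_position = integer(0),
             hairpin_offset = integer(0), vcf_ref = character(0),
             vcf_alt = character(0), sense_ref = character(0),
             sense_alt = character(0), substitution = character(0),
             is_transition = logical(0), ambiguous = logical(0))
}

#' Classify every SNP of a variant set against an annotation
#'
#' Indels and complex variants are carried through ingest but excluded here;
#' only biallelic SNPs enter the miRNA-SNP statistics.
#'
#' @param vs a `variant_set` from [read_vcf()].
#' @param ann a `mirna_annotation`.
#' @param strand_convention report substitutions on the miRNA sense strand
#'   (`"sense"`, default) or on the VCF reference strand (`"vcf_ref"`).
#' @return data.frame of compartment calls (see [classify_snp()]), one row
#'   per SNP-precursor placement, with a `substitution` column in the chosen
#'   convention.
#' @export
classify_variants <- function(vs, ann,
                              strand_convention = c("sense", "vcf_ref")) {
  strand_convention <- match.arg(strand_convention)
  snps <- vs$variants[vs$variants$class == "SNP", , drop = FALSE]
  if (nrow(snps) == 0) return(empty_calls())
  calls <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i)
    classify_snp(snps[i, ], ann)))
  if (is.null(calls) || nrow(calls) == 0) return(empty_calls())
  if (strand_convention == "vcf_ref")
    calls$substitution <- paste0(calls$vcf_ref, ">", calls$vcf_alt)
  rownames(calls) <- NULL
  calls
}

#' Substitution spectrum and transition/transversion fractions
#'
#' Tabulates the twelve ordered base substitutions over a set of compartment
#' calls, either over the whole precursor (`precursor_all`) or restricted to
#' calls within mature miRNAs (`mature_only`), and reports the
#' transition/transversion split as percentages.
#'
#' @param calls compartment-call data.frame from [classify_variants()].
#' @param scope `"precursor_all"` or `"mature_only"`.
#' @return list with `counts` (named vector over the 12 classes), `n`,
#'   `n_transitions`, `n_transversions`, `ts_percent`, `tv_percent`
#'   (percentages rounded to one decimal; zero totals give an explicit
#'   all-zero spectrum).
#' @export
substitution_spectrum <- function(calls,
                                 scope = c("precursor_all", "mature_only")) {
  scope <- match.arg(scope)
  if (scope == "mature_only")
    calls <- calls[calls$compartment %in% c("seed", "mature_nonseed"), ,
                   drop = FALSE]
  # deduplicate by genomic site so a SNP under two precursors counts once
  calls <- calls[!duplicated(calls[c("chrom", "pos")]), , drop = FALSE]
  counts <- table(factor(rna_to_dna(calls$substitution),
                         levels = SUBSTITUTION_CLASSES))
  counts <- stats::setNames(as.integer(counts), SUBSTITUTION_CLASSES)
  n <- sum(counts)
  n_ts <- sum(calls$is_transition)
  list(counts = counts, n = n, n_transitions = n_ts,
       n_transversions = n - n_ts,
       ts_percent = if (n) round(100 * n_ts / n, 1) else 0,
       tv_percent = if (n) round(100 * (n - n_ts) / n, 1) else 0)
}

#' Compartment counts, percentages, and unique-precursor fraction
#'
#' Given compartment calls (or bare counts), reports the number and
#' percentage of SNPs per compartment (percentages of the total SNP calls,
#' one decimal) and the number of distinct precursors carrying a SNP as a
#' fraction of all annotated precursors.
#'
#' @param calls compartment-call data.frame, or a numeric vector of three
#'   counts `(seed, mature_nonseed, precursor_nonmature)`.
#' @param n_precursors total annotated precursors (for the unique-precursor
#'   percentage); taken from `ann` when a call table is given.
#' @param ann optional `mirna_annotation` supplying `n_precursors`.
#' @return list with `counts`, `percent` (both named by compartment),
#'   `n_snps`, `n_unique_precursors`, `unique_precursor_percent`.
#' @export
compartment_summary <- function(calls, n_precursors = NULL, ann = NULL) {
  comps <- c("seed", "mature_nonseed", "precursor_nonmature")
  if (is.numeric(calls)) {
    counts <- stats::setNames(as.integer(calls), comps)
    n_unique <- NA_integer_
  } else {
    calls <- calls[order(match(calls$compartment, comps)), , drop = FALSE]
    dedup <- calls[!duplicated(calls[c("chrom", "pos", "precursor_id")]), ,
                   drop = FALSE]
    site <- dedup[!duplicated(dedup[c("chrom", "pos")]), , drop = FALSE]
    counts <- table(factor(site$compartment, levels = comps))
    counts <- stats::setNames(as.integer(counts), comps)
    n_unique <- length(unique(dedup$precursor_id))
  }
  if (is.null(n_precursors) && !is.null(ann))
    n_precursors <- nrow(ann$precursors)
  n <- sum(counts)
  pct <- if (n) round(100 * counts / n, 1) else stats::setNames(rep(0, 3), comps)
  list(counts = counts, percent = pct, n_snps = n,
       n_unique_precursors = n_unique,
       unique_precursor_percent = if (!is.null(n_precursors) && !is.na(n_unique))
         round(100 * n_unique / n_precursors, 1) else NA_real_)
}
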