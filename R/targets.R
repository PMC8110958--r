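#' Extract the 7-nt seed of a mature miRNA, optionally SNP-altered
#'
#' The seed is mature positions 2-8 (1-based from the mature 5' end) read on
#' the sense strand. With a compartment call supplied, the altered base is
#' substituted at its mature position; calls outside positions 2-8 are an
#' error because they cannot alter the seed.
#'
#' @param ann a `mirna_annotation` with hairpins attached.
#' @param mature_id mature miRNA identifier.
#' @param snp optional one-row compartment call lying in this mature's seed.
#' @return list of class `seed_spec`: `mirna_id`, `seed7` (7-nt RNA),
#'   `variant_label` (`"reference"` or `"snp_altered"`).
#' @export
extract_seed <- function(ann, mature_id, snp = NULL) {
  mt <- ann$matures[ann$matures$mature_id == mature_id, ]
  if (nrow(mt) != 1) stop("unknown or ambiguous mature id: ", mature_id)
  pre <- ann$precursors[ann$precursors$precursor_id == mt$precursor_id, ]
  hp <- ann$hairpins[[mt$precursor_id]]
  if (is.null(hp)) stop("no hairpin sequence attached for ", mt$precursor_id)
  m_off <- if (pre$strand == "+") mt$start - pre$start else pre$end - mt$end
  m_len <- mt$end - mt$start
  if (m_len < 8) stop("mature ", mature_id, " shorter than 8 nt")
  mature_seq <- substr(hp, m_off + 1, m_off + m_len)
  seed7 <- substr(mature_seq, 2, 8)
  label <- "reference"
  if (!is.null(snp)) {
    mp <- snp$mature_position
    if (is.na(mp) || mp < 2 || mp > 8)
      stop("SNP is not in seed positions 2-8 (mature position ",
           mp %||% NA, ")")
    idx <- mp - 1  # position within seed7
    if (substr(seed7, idx, idx) != dna_to_rna(snp$sense_ref))
      stop("seed base at mature position ", mp,
           " does not match the call's sense reference allele")
    substr(seed7, idx, idx) <- dna_to_rna(snp$sense_alt)
    label <- "snp_altered"
  }
  structure(list(mirna_id = mature_id, seed7 = seed7, variant_label = label),
            class = "seed_spec")
}

#' @exportS3Method base::print
print.seed_spec <- function(x, ...) {
  cat("seed_spec:", x$mirna_id, x$seed7, paste0("(", x$variant_label, ")"), "\n")
  invisible(x)
}

seed_site_patterns <- function(seed7) {
  if (nchar(seed7) != 7) stop("seed must be exactly 7 nt (mature positions 2-8)")
  core7 <- revcomp(rna_to_dna(seed7), "dna")          # match to positions 2-8
  core6 <- revcomp(rna_to_dna(substr(seed7, 1, 6)), "dna")  # positions 2-7
  list(`6mer` = core6,
       `7mer_m8` = core7,
       `7mer_A1` = paste0(core6, "A"),
       `8mer` = paste0(core7, "A"))
}

#' Canonical seed-match target prediction over a 3'UTR set
#'
#' A gene is a target iff its 3'UTR (DNA, sense strand, 5'->3') contains at
#' least one site of the requested type: 6mer (match to seed positions 2-7),
#' 7mer-m8 (positions 2-8), 7mer-A1 (positions 2-7 plus an A opposite
#' position 1), 8mer (both), or `any7plus` (default; the union of the three
#' sites of length >= 7). Multiple sites in one UTR count once.
#'
#' @param seed a `seed_spec` from [extract_seed()] (or a bare 7-nt RNA
#'   string).
#' @param utrs named character vector of 3'UTR DNA sequences, gene-keyed.
#' @param site_rule site stringency, see above.
#' @return character vector of target gene ids (sorted).
#' @export
match_targets <- function(seed, utrs,
                          site_rule = c("any7plus", "6mer", "7mer_m8",
                                        "7mer_A1", "8mer")) {
  site_rule <- match.arg(site_rule)
  seed7 <- if (inherits(seed, "seed_spec")) seed$seed7 else seed
  pats <- seed_site_patterns(seed7)
  utrs <- toupper(utrs)
  hit_one <- function(pat) grepl(pat, utrs, fixed = TRUE)
  hits <- switch(site_rule,
    `6mer` = hit_one(pats$`6mer`),
    `7mer_m8` = hit_one(pats$`7mer_m8`),
    `7mer_A1` = hit_one(pats$`7mer_A1`),
    `8mer` = hit_one(pats$`8mer`),
    any7plus = hit_one(pats$`7mer_m8`) | hit_one(pats$`7mer_A1`) |
               hit_one(pats$`8mer`))
  sort(names(utrs)[hits])
}

#' Gained / lost / common targets between reference and SNP-altered seeds
#'
#' @param ref_targets,alt_targets character vectors of target gene ids for
#'   the reference and SNP-altered seed over a shared gene universe.
#' @param mirna_id optional label.
#' @return object of class `target_switch`: list with `mirna_id`,
#'   `targets_ref`, `targets_alt`, `common`, `lost`, `gained` and a `counts`
#'   vector. The set identities `|ref| = |common| + |lost|` and
#'   `|alt| = |common| + |gained|` hold by construction.
#' @export
switch_analysis <- function(ref_targets, alt_targets, mirna_id = NA_character_) {
  ref_targets <- unique(ref_targets); alt_targets <- unique(alt_targets)
  common <- sort(intersect(ref_targets, alt_targets))
  lost <- sort(setdiff(ref_targets, alt_targets))
  gained <- sort(setdiff(alt_targets, ref_targets))
  structure(list(mirna_id = mirna_id,
                 targets_ref = sort(ref_targets),
                 targets_alt = sort(alt_targets),
                 common = common, lost = lost, gained = gained,
                 counts = c(n_ref = length(ref_targets),
                            n_alt = length(alt_targets),
                            n_common = length(common),
                            n_lost = length(lost),
                            n_gained = length(gained))),
            class = "target_switch")
}

#' @exportS3Method base::print
print.target_switch <- function(x, ...) {
  cat("target_switch", if (!is.na(x$mirna_id)) paste0("(", x$mirna_id, ")"), ":\n")
  print(x$counts)
  invisible(x)
}
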