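#' Read a VCF and apply the hard filters of the variant-calling stage
#'
#' Reads a VCF 4.x file, applies the site-level total-depth filter
#' (`DP > min_dp`, exclusive) and the genotype-level quality filter
#' (genotypes with `GQ <= min_gq` are set to missing rather than dropping
#' the record), splits multi-allelic records into biallelic per-alt records,
#' and classifies each record as SNP / insertion / deletion / complex.
#'
#' Coordinates are kept 1-based as in the source (`pos`) alongside the
#' package-internal 0-based position (`pos0 = pos - 1`).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param min_dp site total-depth threshold; records are kept iff
#'   `DP > min_dp`. Default 5.
#' @param min_gq genotype-quality threshold; genotypes are kept iff
#'   `GQ > min_gq`. Default 30.
#' @param on_missing what to do when DP or GQ is absent from a record:
#'   `"error"` (strict, default) or `"pass"` (treat as passing).
#' @return an object of class `variant_set`: list with
#'   \describe{
#'     \item{variants}{data.frame `chrom`, `pos`, `pos0`, `ref`, `alt`,
#'       `class`, `dp` (one row per biallelic record).}
#'     \item{gt}{integer matrix (records x samples) of alt-allele dosages
#'       0/1/2, `NA` = missing.}
#'     \item{samples}{sample names.}
#'   }
#' @export
read_vcf <- function(path, min_dp = 5, min_gq = 30,
                     on_missing = c("error", "pass")) {
  on_missing <- match.arg(on_missing)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF drops to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) stop("no records in VCF: ", path)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  if (anyNA(dp)) {
    if (on_missing == "error")
      stop("missing INFO/DP in VCF record(s): line(s) ",
           paste(utils::head(which(is.na(dp)), 5), collapse = ", "))
    dp[is.na(dp)] <- Inf
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  if (is.null(gq) || all(is.na(gq))) {
    if (on_missing == "error") stop("missing FORMAT/GQ in VCF: ", path)
    gq <- matrix(Inf, nrow = n, ncol = ncol(gt_raw))
  }
  gq[is.na(gq)] <- if (on_missing == "pass") Inf else NA

  keep <- which(dp > min_dp)
  samples <- colnames(gt_raw)

  rows <- list(); gts <- list()
  for (r in keep) {
    ref <- toupper(fix$REF[r])
    alts <- toupper(strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]])
    raw <- gt_raw[r, ]
    parts <- strsplit(raw, "[/|]")
    for (k in seq_along(alts)) {
      # genotype re-coded against alt k; alleles of another alt -> missing
      dos <- vapply(parts, function(a) {
        if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_integer_)
        ai <- suppressWarnings(as.integer(a))
        if (anyNA(ai)) return(NA_integer_)
        if (any(!ai %in% c(0L, k))) return(NA_integer_)
        sum(ai == k)
      }, integer(1))
      dos[is.na(gq[r, ]) | gq[r, ] <= min_gq] <- NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        pos0 = as.integer(fix$POS[r]) - 1L,
        ref = ref, alt = alts[k],
        class = classify_alleles(ref, alts[k]),
        dp = if (is.finite(dp[r])) as.integer(dp[r]) else NA_integer_,
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1]] <- dos
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), pos0 = integer(0),
               ref = character(0), alt = character(0), class = character(0),
               dp = integer(0))
  gt <- if (length(gts)) do.call(rbind, gts) else
    matrix(integer(0), ncol = length(samples))
  colnames(gt) <- samples
  structure(list(variants = variants, gt = gt, samples = samples),
            class = "variant_set")
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "records,",
      length(x$samples), "samples\n")
  print(table(x$variants$class))
  invisible(x)
}

#' Read a miRBase-dialect GFF3 of miRNA annotations
#'
#' Parses precursor features (`miRNA_primary_transcript`) and mature
#' features (`miRNA`), attaches matures to their precursor by
#' `Derives_from` (falling back to coordinate containment), and converts the
#' 1-based inclusive GFF coordinates to the package-internal 0-based
#' half-open convention. Orphan matures (contained in no precursor) trigger
#' a warning and are listed in the `orphans` element; duplicate precursor
#' identifiers are an error.
#'
#' @param path path to a GFF3 file.
#' @return an object of class `mirna_annotation`: list with
#'   \describe{
#'     \item{precursors}{data.frame `precursor_id`, `chrom`, `start`, `end`
#'       (0-based half-open), `strand`.}
#'     \item{matures}{data.frame `mature_id`, `precursor_id`, `chrom`,
#'       `start`, `end`, `strand`.}
#'     \item{hairpins}{named list of sense-strand RNA sequences (empty until
#'       [attach_hairpins()] is called).}
#'     \item{orphans}{mature ids attached to no precursor.}
#'   }
#' @export
read_mirna_gff <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  name_of <- function(d) {
    nm <- if ("Name" %in% names(d)) as.character(d$Name) else rep(NA, nrow(d))
    id <- if ("ID" %in% names(d)) as.character(d$ID) else rep(NA, nrow(d))
    ifelse(is.na(nm) | nm == "", id, nm)
  }
  pre <- df[df$type == "miRNA_primary_transcript", ]
  mat <- df[df$type == "miRNA", ]
  if (nrow(pre) == 0) stop("no miRNA_primary_transcript features in ", path)
  if (!all(pre$strand %in% c("+", "-")))
    stop("precursor features must be stranded (+/-)")
  pre_name <- name_of(pre)
  if (anyDuplicated(pre_name))
    stop("duplicate precursor IDs in GFF: ",
         paste(unique(pre_name[duplicated(pre_name)]), collapse = ", "))
  precursors <- data.frame(
    precursor_id = pre_name, chrom = pre$seqnames,
    start = pre$start - 1L, end = pre$end,  # 1-based inclusive -> 0-based half-open
    strand = pre$strand, stringsAsFactors = FALSE)
  pre_gff_id <- if ("ID" %in% names(pre)) as.character(pre$ID) else pre_name

  matures <- data.frame(mature_id = character(0), precursor_id = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
  orphans <- character(0)
  if (nrow(mat)) {
    mat_name <- name_of(mat)
    derives <- if ("Derives_from" %in% names(mat))
      as.character(mat$Derives_from) else rep(NA_character_, nrow(mat))
    host <- rep(NA_character_, nrow(mat))
    idx <- match(derives, pre_gff_id)
    host[!is.na(idx)] <- precursors$precursor_id[idx[!is.na(idx)]]
    for (r in which(is.na(host))) {  # containment fallback
      hit <- which(precursors$chrom == mat$seqnames[r] &
                   precursors$strand == mat$strand[r] &
                   precursors$start <= mat$start[r] - 1L &
                   precursors$end >= mat$end[r])
      if (length(hit)) host[r] <- precursors$precursor_id[hit[1]]
    }
    orphans <- mat_name[is.na(host)]
    if (length(orphans))
      warning("mature feature(s) contained in no precursor: ",
              paste(orphans, collapse = ", "))
    keep <- !is.na(host)
    matures <- data.frame(
      mature_id = mat_name[keep], precursor_id = host[keep],
      chrom = mat$seqnames[keep], start = mat$start[keep] - 1L,
      end = mat$end[keep], strand = mat$strand[keep],
      stringsAsFactors = FALSE)
    bad <- merge(matures, precursors, by = "precursor_id",
                 suffixes = c(".m", ".p"))
    bad <- bad[bad$start.m < bad$start.p | bad$end.m > bad$end.p, ]
    if (nrow(bad))
      warning("mature(s) extending beyond their precursor: ",
              paste(bad$mature_id, collapse = ", "))
  }
  structure(list(precursors = precursors, matures = matures,
                 hairpins = list(), orphans = orphans),
            class = "mirna_annotation")
}

#' @exportS3Method base::print
print.mirna_annotation <- function(x, ...) {
  cat("mirna_annotation:", nrow(x$precursors), "precursors,",
      nrow(x$matures), "matures,",
      length(x$hairpins), "hairpin sequences\n")
  invisible(x)
}

#' Attach hairpin precursor sequences to an annotation
#'
#' @param ann a `mirna_annotation`.
#' @param fasta path to a hairpin FASTA (ids must match precursor ids) or a
#'   named character vector of sequences. Sequences are converted to the RNA
#'   alphabet; each must be exactly as long as its precursor interval.
#' @return the annotation with `hairpins` populated.
#' @export
attach_hairpins <- function(ann, fasta) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_fasta(fasta, as_rna = TRUE) else dna_to_rna(fasta)
  miss <- setdiff(ann$precursors$precursor_id, names(seqs))
  if (length(miss))
    stop("no hairpin sequence for precursor(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  widths <- ann$precursors$end - ann$precursors$start
  lens <- nchar(seqs[ann$precursors$precursor_id])
  bad <- which(lens != widths)
  if (length(bad))
    stop("hairpin length != precursor interval length for: ",
         paste(ann$precursors$precursor_id[bad], collapse = ", "))
  ann$hairpins <- as.list(seqs[ann$precursors$precursor_id])
  ann
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @param as_rna convert T to U (for hairpin precursors). Genome and UTR
#'   sequences stay DNA.
#' @return named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, as_rna = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for FASTA id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  names(seqs) <- ids
  if (as_rna) seqs <- dna_to_rna(seqs)
  seqs
}

#' Read a BED file of targeted regions
#'
#' BED is already 0-based half-open, matching the internal convention; no
#' coordinate shift is applied.
#'
#' @param path BED path (>= 3 columns).
#' @return data.frame `chrom`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (any(out$start >= out$end)) stop("BED interval with start >= end in ", path)
  out
}

#' Write report tables and summaries to disk
#'
#' Data frames become TSV files; everything else is serialised into a single
#' JSON summary.
#'
#' @param tables named list of data.frames and/or summary lists.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scalars <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    } else scalars[[nm]] <- x
  }
  if (length(scalars)) {
    p <- file.path(dir, "summary.json")
    jsonlite::write_json(scalars, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a TSV written by [write_report()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
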