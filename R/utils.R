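`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Convert between DNA and RNA alphabets
#'
#' Thin helpers used at format boundaries: hairpin precursors are carried as
#' sense-strand RNA (5'->3'), genome and 3'UTR sequences as DNA.
#'
#' @param x character vector of sequences.
#' @return character vector in the requested alphabet (upper case).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement
#'
#' @param x character vector of sequences (single strings).
#' @param alphabet `"dna"` or `"rna"`.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  comp <- if (alphabet == "dna") chartr("ACGT", "TGCA", x) else chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), character(1))
}

#' Complement a single base (vectorised over bases)
#' @param b character vector of single bases.
#' @param alphabet `"dna"` or `"rna"`.
#' @return complemented bases.
#' @export
complement_base <- function(b, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") chartr("ACGT", "TGCA", toupper(b)) else chartr("ACGU", "UGCA", toupper(b))
}

#' Parse dot-bracket notation into a pair table
#'
#' @param structure a dot-bracket string (characters `.` `(` `)`).
#' @return integer vector `p` with `p[i]` the 1-based partner of base `i`,
#'   `NA` for unpaired bases.
#' @export
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("invalid dot-bracket character in structure")
  p <- rep(NA_integer_, length(ch))
  stk <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stk)) stop("unbalanced dot-bracket: unmatched '('")
  p
}

#' Base-pair set of a structure
#' @param structure dot-bracket string.
#' @return two-column integer matrix of pairs (i < j, 1-based).
#' @export
pair_set <- function(structure) {
  p <- parse_dotbracket(structure)
  i <- which(!is.na(p) & seq_along(p) < p)
  cbind(i = i, j = p[i])
}

#' Percent coverage of a targeted design
#'
#' Plain coverage arithmetic: covered base pairs over total targeted base
#' pairs, reported as a percentage at one decimal.
#'
#' @param covered_bp base pairs covered by probes.
#' @param total_bp total targeted base pairs.
#' @return percentage (0-100), rounded to one decimal.
#' @export
coverage_percent <- function(covered_bp, total_bp) {
  stopifnot(total_bp > 0, covered_bp >= 0)
  round(100 * covered_bp / total_bp, 1)
}

is_snp_alleles <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 & ref != alt &
    ref %in% DNA_BASES & alt %in% DNA_BASES
}

classify_alleles <- function(ref, alt) {
  ifelse(is_snp_alleles(ref, alt), "SNP",
    ifelse(nchar(ref) == 1 & nchar(alt) > 1 & substr(alt, 1, 1) == ref, "insertion",
      ifelse(nchar(ref) > 1 & nchar(alt) == 1 & substr(ref, 1, 1) == alt, "deletion",
        "complex")))
}

#' Transition test for a substitution
#' @param ref,alt single bases (DNA or RNA alphabet).
#' @return logical; `TRUE` for purine<->purine or pyrimidine<->pyrimidine.
#' @export
is_transition <- function(ref, alt) {
  r <- rna_to_dna(ref); a <- rna_to_dna(alt)
  (r == "A" & a == "G") | (r == "G" & a == "A") |
    (r == "C" & a == "T") | (r == "T" & a == "C")
}

SUBSTITUTION_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                          "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
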