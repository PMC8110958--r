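normalize_annotation <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(ncol(annotation) >= 2)
    split(as.character(annotation[[1]]), as.character(annotation[[2]]))
  } else annotation
}

#' Hypergeometric (over-representation) GO-term enrichment
#'
#' For each term with K annotated genes in a universe of N, and a target set
#' of n genes of which k carry the term, computes the upper-tail
#' hypergeometric probability `P(X >= k)` and applies Benjamini-Hochberg FDR
#' across all tested terms. Terms with `K = 0` are skipped; an empty target
#' set yields an empty table. Depletion is not tested.
#'
#' @param targets character vector of target gene ids (must lie in the
#'   universe).
#' @param annotation two-column data.frame `(gene, term)` or a named list
#'   term -> gene vector.
#' @param universe gene universe; default: all annotated genes.
#' @param term_names optional named vector term -> human-readable name.
#' @return data.frame sorted by p-value: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `fdr`.
#' @export
hypergeom_enrich <- function(targets, annotation, universe = NULL,
                             term_names = NULL) {
  ann <- normalize_annotation(annotation)
  ann <- lapply(ann, unique)
  if (is.null(universe)) universe <- sort(unique(unlist(ann)))
  universe <- unique(universe)
  bad <- setdiff(targets, universe)
  if (length(bad))
    stop("target gene(s) outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  targets <- unique(targets)
  N <- length(universe); n <- length(targets)
  if (n == 0)
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0), fdr = numeric(0)))
  rows <- lapply(names(ann), function(term) {
    genes <- intersect(ann[[term]], universe)
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(genes, targets))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = unname(term_names[term] %||% term),
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Compare enrichment between reference and SNP-altered target sets
#'
#' Classifies each term significant in either run (at `alpha` on `measure`)
#' as present in the reference run only, the altered run only, or both, and
#' reports the per-term annotated-target counts `k_ref` / `k_alt`.
#'
#' @param rows_ref,rows_alt enrichment tables from [hypergeom_enrich()] run
#'   with the same annotation and universe.
#' @param alpha significance threshold (default 0.05).
#' @param measure `"fdr"` (default) or `"p_value"`.
#' @return data.frame `term_id`, `term_name`, `status`
#'   (`ref_only`/`alt_only`/`both`), `k_ref`, `k_alt`, `measure_ref`,
#'   `measure_alt`, sorted by status then term.
#' @export
compare_enrichment <- function(rows_ref, rows_alt, alpha = 0.05,
                               measure = c("fdr", "p_value")) {
  measure <- match.arg(measure)
  if (nrow(rows_ref) && nrow(rows_alt) && rows_ref$N[1] != rows_alt$N[1])
    stop("enrichment runs use different universes (N mismatch)")
  sig_ref <- rows_ref$term_id[rows_ref[[measure]] <= alpha]
  sig_alt <- rows_alt$term_id[rows_alt[[measure]] <= alpha]
  terms <- union(sig_ref, sig_alt)
  if (!length(terms))
    return(data.frame(term_id = character(0), term_name = character(0),
                      status = character(0), k_ref = integer(0),
                      k_alt = integer(0), measure_ref = numeric(0),
                      measure_alt = numeric(0)))
  iref <- match(terms, rows_ref$term_id)
  ialt <- match(terms, rows_alt$term_id)
  status <- ifelse(terms %in% sig_ref & terms %in% sig_alt, "both",
                   ifelse(terms %in% sig_ref, "ref_only", "alt_only"))
  out <- data.frame(
    term_id = terms,
    term_name = ifelse(!is.na(iref), rows_ref$term_name[iref],
                       rows_alt$term_name[ialt]),
    status = status,
    k_ref = ifelse(!is.na(iref), rows_ref$k[iref], NA_integer_),
    k_alt = ifelse(!is.na(ialt), rows_alt$k[ialt], NA_integer_),
    measure_ref = ifelse(!is.na(iref), rows_ref[[measure]][iref], NA_real_),
    measure_alt = ifelse(!is.na(ialt), rows_alt[[measure]][ialt], NA_real_),
    stringsAsFactors = FALSE)
  out[order(out$status, out$term_id), ]
}

#' Read a two-column gene -> GO-term annotation TSV
#'
#' @param path TSV with columns `gene` and `term` (header optional but
#'   expected by default).
#' @return data.frame `gene`, `term`.
#' @export
read_go_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(tab))) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(tab)[1:2] <- c("gene", "term")
  }
  tab[c("gene", "term")]
}
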