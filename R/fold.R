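PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

.param_cache <- new.env(parent = emptyenv())

#' Nearest-neighbor energy parameters for the loop_energy engine
#'
#' Loads the simplified Turner-style parameter set shipped with the package
#' (stacking table over the six canonical pairs, hairpin/bulge/internal loop
#' length penalties with Jacobson-Stockmayer extrapolation, affine multiloop
#' terms). Values are in kcal/mol.
#'
#' @param path optional path to an alternative parameter TSV with columns
#'   `category`, `key1`, `key2`, `value`.
#' @return a list with elements `stack` (6x6 matrix), `hairpin`, `bulge`,
#'   `internal` (length tables), `asym`, `asym_max`, `ml_a`, `ml_b`, `ml_c`,
#'   `lxc`, `maxloop`.
#' @export
loop_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.param_cache$default)) return(.param_cache$default)
    path <- system.file("extdata", "loop_energy_params.tsv", package = "mirsnp")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stk <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  st <- tab[tab$category == "stack", ]
  for (r in seq_len(nrow(st))) stk[st$key1[r], st$key2[r]] <- st$value[r]
  if (anyNA(stk)) stop("incomplete stacking table in ", path)
  pull <- function(cat) {
    x <- tab[tab$category == cat, ]
    x$value[order(as.integer(x$key1))]
  }
  misc <- tab[tab$category == "misc", ]
  mv <- function(k) misc$value[misc$key1 == k]
  p <- list(stack = stk, hairpin = pull("hairpin"), bulge = pull("bulge"),
            internal = pull("internal"), asym = mv("asym"),
            asym_max = mv("asym_max"), ml_a = mv("ml_close"),
            ml_b = mv("ml_branch"), ml_c = mv("ml_unpaired"),
            lxc = mv("lxc"), maxloop = as.integer(mv("maxloop")))
  if (cache) .param_cache$default <- p
  p
}

encode_rna <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, RNA_BASES) - 1L
  if (anyNA(idx))
    stop("invalid RNA alphabet: sequence must contain only A/C/G/U")
  idx
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Three engines share one contract (dot-bracket structure + energy):
#' \describe{
#'   \item{`loop_energy`}{nearest-neighbor free-energy minimisation
#'     (Zuker-style dynamic programming over the shipped parameter set);
#'     energy in kcal/mol. The default.}
#'   \item{`nussinov`}{base-pair maximisation; the reported "energy" is the
#'     pseudo-energy `-(number of pairs)`. Intended for teaching and as a
#'     simple oracle.}
#'   \item{`external`}{a pluggable exact backend; by default shells out to
#'     `RNAfold` (ViennaRNA) if it is on the PATH. Required to reproduce
#'     published RNAfold energies.}
#' }
#' Ties among co-optimal structures are broken deterministically (shortest
#' loops, then 5'-most branches), so repeated calls are bit-identical.
#'
#' @param seq RNA string over A/C/G/U, length >= 10.
#' @param engine one of `"loop_energy"`, `"nussinov"`, `"external"`.
#' @param params energy parameters for `loop_energy`
#'   (see [loop_energy_params()]).
#' @return an object of class `fold_result`: list with `sequence`,
#'   `structure` (dot-bracket), `mfe` (kcal/mol), `engine`.
#' @export
fold_mfe <- function(seq, engine = c("loop_energy", "nussinov", "external"),
                     params = loop_energy_params()) {
  engine <- match.arg(engine)
  seq <- toupper(seq)
  if (nchar(seq) < 10)
    stop("sequence shorter than 10 nt: no meaningful hairpin")
  enc <- encode_rna(seq)  # validates alphabet for every engine
  res <- switch(engine,
    nussinov = fold_nussinov_cpp(enc),
    loop_energy = fold_zuker_cpp(enc, params$stack, params$hairpin,
                                 params$bulge, params$internal, params$asym,
                                 params$asym_max, params$ml_a, params$ml_b,
                                 params$ml_c, params$lxc, params$maxloop),
    external = rnafold_external(seq))
  structure(list(sequence = seq, structure = res$structure,
                 mfe = res$mfe, engine = engine),
            class = "fold_result")
}

#' @exportS3Method base::print
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.2f)", x$mfe), "\n", sep = "")
  cat("engine:", x$engine, "\n")
  invisible(x)
}

#' Is an external RNAfold backend available?
#' @return logical.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

rnafold_external <- function(seq) {
  if (!rnafold_available())
    stop("external engine requested but no 'RNAfold' executable is on the PATH")
  out <- system2("RNAfold", args = c("--noPS"), input = seq, stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", line))[[1]]
  if (length(m) != 3) stop("could not parse RNAfold output: ", line)
  list(structure = m[2], mfe = as.numeric(m[3]))
}

## ---- independent energy evaluation and exhaustive enumeration -------------

#' Free energy of a given structure under the loop-decomposition model
#'
#' Independent evaluator used to validate the dynamic-programming engine:
#' decomposes the structure into hairpin, stacked-pair, bulge, internal and
#' multibranch loops and sums their tabulated energies. Shares the parameter
#' table with [fold_mfe()] but none of its code path.
#'
#' @param seq RNA string.
#' @param db dot-bracket structure of the same length.
#' @param params see [loop_energy_params()].
#' @return energy in kcal/mol (`Inf` for structures the model forbids).
#' @export
structure_energy <- function(seq, db, params = loop_energy_params()) {
  enc <- encode_rna(seq)
  n <- length(enc)
  if (nchar(db) != n) stop("structure length != sequence length")
  p <- parse_dotbracket(db)
  pt <- function(i, j) {
    a <- RNA_BASES[enc[i] + 1]; b <- RNA_BASES[enc[j] + 1]
    key <- paste0(a, b)
    key <- c(CG = "CG", GC = "GC", GU = "GU", UG = "UG", AU = "AU", UA = "UA")[key]
    key
  }
  loop_tab <- function(tab, L) {
    m <- length(tab)
    if (L <= 0) return(Inf)
    if (L <= m) return(tab[L])
    tab[m] + params$lxc * log(L / m)
  }
  ij <- pair_set(db)
  if (nrow(ij)) {
    ok <- !is.na(pt(ij[, 1], ij[, 2])) & (ij[, 2] - ij[, 1] - 1 >= 3)
    if (!all(ok)) return(Inf)
  }
  total <- 0
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    # direct children of pair (i, j)
    children <- matrix(integer(0), ncol = 2)
    unpaired <- 0L
    k <- i + 1
    while (k < j) {
      if (is.na(p[k])) { unpaired <- unpaired + 1L; k <- k + 1 }
      else { children <- rbind(children, c(k, p[k])); k <- p[k] + 1 }
    }
    nc <- nrow(children)
    if (nc == 0) {
      total <- total + loop_tab(params$hairpin, j - i - 1)
    } else if (nc == 1) {
      a <- children[1, 1]; b <- children[1, 2]
      l1 <- a - i - 1; l2 <- j - b - 1
      if (l1 == 0 && l2 == 0) {
        total <- total + params$stack[pt(i, j), pt(a, b)]
      } else if (l1 == 0 || l2 == 0) {
        total <- total + loop_tab(params$bulge, l1 + l2)
      } else {
        total <- total + loop_tab(params$internal, l1 + l2) +
          min(params$asym * abs(l1 - l2), params$asym_max)
      }
    } else {
      total <- total + params$ml_a + params$ml_b * (1 + nc) +
        params$ml_c * unpaired
    }
  }
  total
}

#' Exhaustively enumerate all secondary structures of a short RNA
#'
#' Generates every pseudoknot-free structure over the canonical pairs
#' (Watson-Crick + G.U) with a minimum hairpin loop of 3 nt. Intended as a
#' brute-force oracle for short sequences (roughly n <= 22); the count grows
#' exponentially.
#'
#' @param seq RNA string.
#' @return character vector of dot-bracket strings (includes the open chain).
#' @export
enumerate_structures <- function(seq) {
  enc <- encode_rna(seq)
  n <- length(enc)
  pairable <- function(a, b) {
    s <- paste0(RNA_BASES[a + 1], RNA_BASES[b + 1])
    s %in% c("CG", "GC", "GU", "UG", "AU", "UA")
  }
  memo <- new.env(parent = emptyenv())
  # returns list of pair matrices for interval [i, j]
  gen <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(gen(i + 1, j), identity)  # i unpaired
    for (k in (i + 4):j) {
      if (!pairable(enc[i], enc[k])) next
      inner <- gen(i + 1, k - 1)
      rest <- if (k + 1 <= j) gen(k + 1, j) else list(matrix(integer(0), ncol = 2))
      for (a in inner) for (b in rest)
        out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  structs <- gen(1, n)
  vapply(structs, function(m) {
    db <- rep(".", n)
    if (nrow(m)) { db[m[, 1]] <- "("; db[m[, 2]] <- ")" }
    paste(db, collapse = "")
  }, character(1))
}

## ---- SNP application and delta-delta-G ------------------------------------

#' Substitute a classified SNP into its hairpin sequence
#'
#' Applies the sense-strand substitution of a compartment call to the
#' precursor hairpin at the call's sense offset. The base found at the offset
#' must equal the call's sense reference allele; a mismatch indicates a
#' strand or offset bookkeeping error upstream and is a hard error.
#'
#' @param ann a `mirna_annotation` object with hairpin sequences attached.
#' @param call one row of a compartment-call table (see
#'   [classify_variants()]).
#' @return the SNP-altered hairpin (RNA string).
#' @export
apply_snp_to_hairpin <- function(ann, call) {
  hp <- ann$hairpins[[call$precursor_id]]
  if (is.null(hp)) stop("no hairpin sequence for precursor ", call$precursor_id)
  off <- call$hairpin_offset  # 0-based sense offset
  have <- substr(hp, off + 1, off + 1)
  want <- dna_to_rna(call$sense_ref)
  if (have != want)
    stop(sprintf("reference mismatch in %s at offset %d: hairpin has %s, call says %s",
                 call$precursor_id, off, have, want))
  paste0(substr(hp, 1, off), dna_to_rna(call$sense_alt),
         substr(hp, off + 2, nchar(hp)))
}

#' Fold a hairpin with and without a SNP and quantify the change
#'
#' Folds the reference precursor and the SNP-altered precursor with the same
#' engine and reports the minimum-free-energy change
#' `ddg = MFE(alt) - MFE(ref)` (positive = destabilising), its direction at
#' the one-decimal reporting threshold (|ddg| >= 0.05), and whether the
#' base-pair set of the MFE structure changed.
#'
#' @inheritParams apply_snp_to_hairpin
#' @param engine,params passed to [fold_mfe()].
#' @return one-row data.frame (`ddg_record`): `precursor_id`, `mfe_ref`,
#'   `mfe_alt`, `ddg`, `abs_ddg`, `direction`, `structure_changed`,
#'   `structure_ref`, `structure_alt`.
#' @export
ddg_analysis <- function(ann, call, engine = "loop_energy",
                         params = loop_energy_params()) {
  hp_ref <- ann$hairpins[[call$precursor_id]]
  hp_alt <- apply_snp_to_hairpin(ann, call)
  f_ref <- fold_mfe(hp_ref, engine = engine, params = params)
  f_alt <- fold_mfe(hp_alt, engine = engine, params = params)
  ddg <- f_alt$mfe - f_ref$mfe
  direction <- if (ddg >= 0.05) "increase" else if (ddg <= -0.05) "decrease" else "none"
  changed <- !identical(pair_set(f_ref$structure), pair_set(f_alt$structure))
  data.frame(precursor_id = call$precursor_id, chrom = call$chrom,
             pos = call$pos, compartment = call$compartment,
             sense_ref = call$sense_ref, sense_alt = call$sense_alt,
             mfe_ref = f_ref$mfe, mfe_alt = f_alt$mfe, ddg = ddg,
             abs_ddg = abs(ddg), direction = direction,
             structure_changed = changed,
             structure_ref = f_ref$structure, structure_alt = f_alt$structure,
             stringsAsFactors = FALSE)
}

#' Cohort summary of hairpin free-energy changes
#'
#' Aggregates per-SNP `ddg_record` rows into the cohort-level counts a
#' stability screen reports: how many SNPs changed the MFE at all, in which
#' direction, the mean and range of the nonzero |ddg| values, and how many
#' changed the secondary structure. Precursors carrying more than one SNP
#' are flagged rather than dropped.
#'
#' @param records data.frame of rows from [ddg_analysis()].
#' @return list with `n`, `n_nonzero`, `n_increase`, `n_decrease`, `n_none`,
#'   `mean_abs_ddg` (over nonzero records; 0 with `mean_defined = FALSE` if
#'   none), `min_abs_ddg`, `max_abs_ddg`, `n_structure_changed`,
#'   `multi_snp_precursors`.
#' @export
cohort_ddg_summary <- function(records) {
  nz <- records$abs_ddg >= 0.05
  multi <- names(which(table(records$precursor_id) > 1))
  mean_def <- any(nz)
  list(
    n = nrow(records),
    n_nonzero = sum(nz),
    n_increase = sum(records$direction == "increase"),
    n_decrease = sum(records$direction == "decrease"),
    n_none = sum(records$direction == "none"),
    mean_abs_ddg = if (mean_def) mean(records$abs_ddg[nz]) else 0,
    mean_defined = mean_def,
    min_abs_ddg = if (mean_def) min(records$abs_ddg[nz]) else NA_real_,
    max_abs_ddg = if (mean_def) max(records$abs_ddg[nz]) else NA_real_,
    n_structure_changed = sum(records$structure_changed),
    multi_snp_precursors = multi
  )
}
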