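#' Minor allele frequency from diploid genotype dosages
#'
#' @param gt integer vector of alt-allele dosages (0/1/2, `NA` missing) for
#'   one SNP.
#' @return `min(p, 1 - p)` over called alleles; `NA` if every genotype is
#'   missing (such SNPs are excluded from cohort means with a note).
#' @export
compute_maf <- function(gt) {
  gt <- gt[!is.na(gt)]
  if (!length(gt)) return(NA_real_)
  p <- sum(gt) / (2 * length(gt))
  min(p, 1 - p)
}

#' Observed heterozygosity from diploid genotype dosages
#'
#' @inheritParams compute_maf
#' @return fraction of called genotypes that are heterozygous; `NA` if all
#'   missing.
#' @export
compute_obs_het <- function(gt) {
  gt <- gt[!is.na(gt)]
  if (!length(gt)) return(NA_real_)
  mean(gt == 1)
}

pop_sd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  if (type == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

#' Consecutive inter-SNP distances within chromosomes
#'
#' Distances are absolute position differences between consecutive variants
#' on the same chromosome; cross-chromosome pairs are physically undefined
#' and excluded.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based) columns.
#' @param sd_type divisor convention for the SD (`"population"` = n,
#'   default, matching the plus/minus style of cohort reports).
#' @return list `n_pairs`, `mean_bp`, `sd_bp`, `min_bp`, `max_bp`; all `NA`
#'   with `n_pairs = 0` when no chromosome holds two variants.
#' @export
inter_snp_distances <- function(variants, sd_type = "population") {
  dists <- unlist(lapply(split(variants$pos, variants$chrom), function(p) {
    if (length(p) < 2) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
  if (!length(dists))
    return(list(n_pairs = 0L, mean_bp = NA_real_, sd_bp = NA_real_,
                min_bp = NA_real_, max_bp = NA_real_))
  list(n_pairs = length(dists), mean_bp = mean(dists),
       sd_bp = pop_sd(dists, sd_type), min_bp = min(dists),
       max_bp = max(dists))
}

#' SNP density per kilobase
#'
#' @param n_snps SNP count.
#' @param region_length_bp total region length in bp (> 0).
#' @return SNPs per 1 kb, rounded to one decimal.
#' @export
density_per_kb <- function(n_snps, region_length_bp) {
  if (region_length_bp <= 0) stop("region length must be positive")
  round(n_snps / (region_length_bp / 1000), 1)
}

#' Per-SNP and cohort population summary
#'
#' Computes MAF and observed heterozygosity per SNP, cohort means with SDs
#' (population divisor n by default), inter-SNP distance statistics, and,
#' when region lengths are supplied, SNP densities per kb.
#'
#' @param vs a `variant_set`; only SNP records are summarised.
#' @param region_length_bp optional total length of the surveyed region for
#'   the density.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return list with `per_snp` (data.frame `chrom`, `pos`, `maf`,
#'   `obs_het`), `n_snps`, `n_excluded` (all-missing genotypes), `mean_maf`,
#'   `sd_maf`, `mean_het`, `sd_het`, `distances`, `density_per_kb` (`NA` if
#'   no length given).
#' @export
snp_summary <- function(vs, region_length_bp = NULL,
                        sd_type = "population") {
  idx <- which(vs$variants$class == "SNP")
  per <- data.frame(chrom = vs$variants$chrom[idx],
                    pos = vs$variants$pos[idx],
                    maf = vapply(idx, function(i) compute_maf(vs$gt[i, ]),
                                 numeric(1)),
                    obs_het = vapply(idx, function(i) compute_obs_het(vs$gt[i, ]),
                                     numeric(1)),
                    stringsAsFactors = FALSE)
  excl <- sum(is.na(per$maf))
  if (excl) message(excl, " SNP(s) with all genotypes missing excluded from means")
  ok <- !is.na(per$maf)
  list(per_snp = per, n_snps = nrow(per), n_excluded = excl,
       mean_maf = mean(per$maf[ok]), sd_maf = pop_sd(per$maf[ok], sd_type),
       mean_het = mean(per$obs_het[ok]), sd_het = pop_sd(per$obs_het[ok], sd_type),
       distances = inter_snp_distances(per[ok, , drop = FALSE], sd_type),
       density_per_kb = if (is.null(region_length_bp)) NA_real_ else
         density_per_kb(nrow(per), region_length_bp))
}
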