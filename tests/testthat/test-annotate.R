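make_test_ann <- function() {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(path)
  read_mirna_gff(path)  # file only needed until ingest returns
}

snp_row <- function(chrom, pos0, ref, alt) {
  data.frame(chrom = chrom, pos = pos0 + 1L, pos0 = pos0, ref = ref,
             alt = alt, class = "SNP", dp = 50L, stringsAsFactors = FALSE)
}

test_that("plus-strand SNPs map to seed / mature / precursor compartments", {
  ann <- make_test_ann()
  # mature starts at 110 (0-based): genomic 112 is mature position 3 -> seed
  call <- classify_snp(snp_row("chr1", 112, "C", "T"), ann)
  expect_equal(call$compartment, "seed")
  expect_equal(call$mature_position, 3L)
  expect_equal(call$sense_ref, "C")
  expect_true(call$is_transition)
  # one base 5' of the mature
  expect_equal(classify_snp(snp_row("chr1", 109, "G", "T"), ann)$compartment,
               "precursor_nonmature")
  # mature position 1 and positions >= 9 are mature beyond seed
  expect_equal(classify_snp(snp_row("chr1", 110, "A", "G"), ann)$compartment,
               "mature_nonseed")
  expect_equal(classify_snp(snp_row("chr1", 118, "A", "G"), ann)$compartment,
               "mature_nonseed")
  # outside every precursor -> no call
  expect_equal(nrow(classify_snp(snp_row("chr1", 50, "A", "G"), ann)), 0)
})

test_that("minus-strand positions follow the hand-built position map", {
  ann <- make_test_ann()
  # minus-strand mature occupies genomic (350, 372): position 1 is the
  # genomically rightmost base 371; position p sits at genomic 372 - p
  for (p in 1:22) {
    call <- classify_snp(snp_row("chr1", 372 - p, "C", "T"), ann)
    expect_equal(call$mature_position, p)
    expect_equal(call$compartment,
                 if (p >= 2 && p <= 8) "seed" else "mature_nonseed")
  }
  # VCF C>T reads G>A on the miRNA sense strand: a transition
  call <- classify_snp(snp_row("chr1", 370, "C", "T"), ann)
  expect_equal(call$mature_position, 2L)
  expect_equal(call$sense_ref, "G")
  expect_equal(call$sense_alt, "A")
  expect_equal(call$substitution, "G>A")
  expect_true(call$is_transition)
  # hairpin offset counts from the sense 5' end (genomic right on minus)
  expect_equal(call$hairpin_offset, 380 - 1 - 370)
})

test_that("substitution spectrum counts classes and Ts/Tv fractions", {
  calls <- data.frame(chrom = "chr1", pos = c(1, 2, 3),
                      compartment = "precursor_nonmature",
                      substitution = c("C>T", "G>A", "C>G"),
                      is_transition = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  sp <- substitution_spectrum(calls)
  expect_equal(sp$n, 3)
  expect_equal(sp$n_transitions, 2)
  expect_equal(sp$ts_percent, 66.7)
  expect_equal(unname(sp$counts[c("C>T", "G>A", "C>G")]), c(1L, 1L, 1L))
  # single call: exactly one nonzero class
  sp1 <- substitution_spectrum(calls[2, ])
  expect_equal(sum(sp1$counts > 0), 1)
  # empty scope gives explicit zeros
  sp0 <- substitution_spectrum(calls[calls$compartment == "seed", ])
  expect_equal(sp0$n, 0)
  expect_true(all(sp0$counts == 0))
})

test_that("compartment percentages and unique-precursor fraction", {
  cs <- compartment_summary(c(2, 12, 59), n_precursors = 381)
  # 12/73 is 16.438%: one-decimal rounding gives 16.4
  expect_equal(unname(cs$percent), c(2.7, 16.4, 80.8))
  expect_equal(cs$n_snps, 73)
  # 50 distinct precursors of 381 annotated is 13% at integer precision
  expect_equal(round(100 * 50 / 381), 13)
  # single call: 100% in its compartment
  one <- data.frame(chrom = "chr1", pos = 5, precursor_id = "p1",
                    compartment = "seed", stringsAsFactors = FALSE)
  expect_equal(unname(compartment_summary(one, n_precursors = 10)$percent),
               c(100, 0, 0))
})

test_that("Ts/Tv totals are invariant under strand of the annotation", {
  # same planted cohort geometry on opposite strands
  sim_p <- simulate_cohort(small_config(seed = 5, frac_minus_strand = 0))
  sim_m <- simulate_cohort(small_config(seed = 5, frac_minus_strand = 1))
  spec <- function(sim) {
    vs <- read_vcf(sim$paths$vcf)
    ann <- read_mirna_gff(sim$paths$gff)
    substitution_spectrum(classify_variants(vs, ann))
  }
  sp <- spec(sim_p); sm <- spec(sim_m)
  expect_equal(sp$n_transitions, sm$n_transitions)
  expect_equal(sp$n_transversions, sm$n_transversions)
})

test_that("compartment calls partition the SNPs inside precursors", {
  fi <- full_ingest()
  cs <- compartment_summary(fi$calls, ann = fi$ann)
  n_sites <- nrow(unique(fi$calls[c("chrom", "pos")]))
  expect_equal(sum(cs$counts), n_sites)
  expect_false(any(duplicated(fi$calls[c("chrom", "pos", "precursor_id",
                                         "mature_id")])))
})

test_that("classification recovers every planted compartment exactly", {
  fi <- full_ingest()
  tr <- fi$sim$truth$snps
  m <- merge(tr, fi$calls, by = c("chrom", "pos"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$compartment.x, m$compartment.y)
  expect_equal(rna_to_dna(m$sense_ref.x), rna_to_dna(m$sense_ref.y))
  expect_equal(rna_to_dna(m$sense_alt.x), rna_to_dna(m$sense_alt.y))
  expect_equal(m$is_transition.x, m$is_transition.y)
  expect_equal(m$mature_position.x[!is.na(m$mature_position.x)],
               m$mature_position.y[!is.na(m$mature_position.x)])
  expect_equal(m$precursor_id.x, m$precursor_id.y)
})

test_that("vcf_ref strand convention reports the VCF alleles", {
  fi <- full_ingest()
  calls <- classify_variants(fi$vs, fi$ann, strand_convention = "vcf_ref")
  expect_true(all(calls$substitution ==
                  paste0(calls$vcf_ref, ">", calls$vcf_alt)))
})
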