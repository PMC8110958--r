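test_that("nussinov engine maximises base pairs on known cases", {
  # GGGAAAUCCC: exhaustive enumeration says 3 pairs is the optimum
  bf <- brute_force_mfe("GGGAAAUCCC")
  max_pairs <- max(vapply(bf$structures,
                          function(db) nrow(pair_set(db)), integer(1)))
  expect_equal(max_pairs, 3)
  f <- fold_mfe("GGGAAAUCCC", "nussinov")
  expect_equal(f$mfe, -3)
  expect_equal(nrow(pair_set(f$structure)), 3)
  # no complementary bases: open chain, pseudo-energy 0
  fa <- fold_mfe(strrep("A", 12), "nussinov")
  expect_equal(fa$mfe, 0)
  expect_equal(fa$structure, strrep(".", 12))
  expect_equal(fold_mfe(strrep("A", 12), "loop_energy")$mfe, 0)
})

test_that("fold_mfe validates its input", {
  expect_error(fold_mfe("ACGUACGU"), "shorter")
  expect_error(fold_mfe("ACGTACGTACGT"), "alphabet")   # DNA rejected
  expect_error(fold_mfe("ACGUNCGUACGU"), "alphabet")
})

test_that("loop_energy MFE structure is achievable and optimal (spot check)", {
  set.seed(23)
  for (r in 1:30) {
    s <- random_rna(sample(10:17, 1))
    f <- fold_mfe(s, "loop_energy")
    bf <- brute_force_mfe(s)
    expect_equal(f$mfe, bf$mfe, tolerance = 1e-9)
    expect_equal(structure_energy(s, f$structure), f$mfe, tolerance = 1e-9)
  }
})

test_that("folding is deterministic", {
  set.seed(3)
  s <- make_hairpin(28, 9)
  for (engine in c("loop_energy", "nussinov")) {
    f1 <- fold_mfe(s, engine); f2 <- fold_mfe(s, engine)
    expect_identical(f1$structure, f2$structure)
    expect_identical(f1$mfe, f2$mfe)
  }
})

test_that("SNP application substitutes exactly one sense base with a guard", {
  fi <- full_ingest()
  calls <- fi$calls
  for (i in sample(nrow(calls), 20)) {
    hp <- fi$ann$hairpins[[calls$precursor_id[i]]]
    alt <- apply_snp_to_hairpin(fi$ann, calls[i, ])
    expect_equal(nchar(alt), nchar(hp))
    diffs <- which(strsplit(hp, "")[[1]] != strsplit(alt, "")[[1]])
    expect_equal(diffs, calls$hairpin_offset[i] + 1)
    expect_equal(substr(alt, diffs, diffs), dna_to_rna(calls$sense_alt[i]))
  }
  # reference-mismatch guard fires on corrupted calls
  bad <- calls[1, ]
  bad$sense_ref <- setdiff(c("A", "C", "G", "U"),
                           dna_to_rna(bad$sense_ref))[1]
  expect_error(apply_snp_to_hairpin(fi$ann, bad), "mismatch")
})

test_that("ddG is antisymmetric under allele swap and zero for identity", {
  fi <- full_ingest()
  calls <- fi$calls
  set.seed(41)
  for (i in sample(nrow(calls), 12)) {
    fwd <- ddg_analysis(fi$ann, calls[i, ])
    # swap: fold from the altered hairpin back to the reference
    swapped <- calls[i, ]
    swapped$sense_ref <- calls$sense_alt[i]
    swapped$sense_alt <- calls$sense_ref[i]
    ann_alt <- fi$ann
    ann_alt$hairpins[[calls$precursor_id[i]]] <-
      apply_snp_to_hairpin(fi$ann, calls[i, ])
    rev <- ddg_analysis(ann_alt, swapped)
    expect_equal(rev$ddg, -fwd$ddg, tolerance = 1e-9)
  }
})

test_that("planted stem-disrupting SNPs destabilise; loop SNPs are neutral", {
  fi <- full_ingest()
  tr <- fi$sim$truth$snps
  calls <- merge(fi$calls, tr[c("chrom", "pos", "ddg_class")],
                 by = c("chrom", "pos"))
  stem <- calls[calls$ddg_class == "stem_disrupt", ]
  loopn <- calls[calls$ddg_class == "loop_neutral", ]
  expect_gt(nrow(stem), 0)
  expect_gt(nrow(loopn), 0)
  for (i in seq_len(nrow(stem))) {
    d <- ddg_analysis(fi$ann, stem[i, ])
    expect_gt(d$ddg, 0)                  # breaking a WC stem pair costs energy
    expect_true(d$structure_changed)
    expect_equal(d$direction, "increase")
  }
  for (i in seq_len(nrow(loopn))) {
    d <- ddg_analysis(fi$ann, loopn[i, ])
    expect_equal(d$direction, "none")    # loop bases carry no energy terms
    expect_false(d$structure_changed)
  }
})

test_that("a structure change can accompany a near-zero energy change", {
  # frozen case found by search: the substitution creates a second helix
  # while shifting the MFE by only 0.1 kcal/mol
  s_ref <- "UCCCCGGCUUCGGUAUGAAUUGACAGCUAGCUCAGCGCAG"
  s_alt <- s_ref; substr(s_alt, 37, 37) <- "U"
  f_ref <- fold_mfe(s_ref); f_alt <- fold_mfe(s_alt)
  ddg <- f_alt$mfe - f_ref$mfe
  expect_equal(round(abs(ddg), 1), 0.1)
  expect_false(identical(pair_set(f_ref$structure), pair_set(f_alt$structure)))
})

test_that("cohort ddG summary aggregates directions and magnitudes", {
  recs <- data.frame(precursor_id = c("a", "b", "c"),
                     ddg = c(1, -2, 0), abs_ddg = c(1, 2, 0),
                     direction = c("increase", "decrease", "none"),
                     structure_changed = c(TRUE, TRUE, FALSE))
  s <- cohort_ddg_summary(recs)
  expect_equal(s$n_nonzero, 2)
  expect_equal(s$mean_abs_ddg, 1.5)
  expect_equal(s$n_increase, 1)
  expect_equal(s$n_decrease, 1)
  # all-zero cohort: mean flagged undefined, reported as 0
  z <- cohort_ddg_summary(data.frame(precursor_id = "a", ddg = 0, abs_ddg = 0,
                                     direction = "none",
                                     structure_changed = FALSE))
  expect_equal(z$mean_abs_ddg, 0)
  expect_false(z$mean_defined)
  # multi-SNP precursors flagged, not dropped
  recs2 <- rbind(recs, recs[1, ])
  expect_equal(cohort_ddg_summary(recs2)$multi_snp_precursors, "a")
})

test_that("external engine honours the fold contract when present", {
  skip_if_not(rnafold_available(), "RNAfold not on PATH")
  set.seed(77)
  s <- make_hairpin(30, 10)
  f <- fold_mfe(s, "external")
  expect_equal(nchar(f$structure), nchar(s))
  expect_lt(f$mfe, -10)                        # a designed stem is stable
  expect_gt(nrow(pair_set(f$structure)), 20)
})
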