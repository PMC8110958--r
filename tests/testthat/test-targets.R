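# A/C background cannot form accidental sites for seeds whose complementary
# cores contain a G or T (true of every seed used below)
utr_with <- function(..., pad = 30) {
  set.seed(123)
  parts <- list(...)
  paste0(paste(sample(c("A", "C"), pad, TRUE), collapse = ""),
         paste(unlist(parts), collapse =
                 paste(sample(c("A", "C"), 10, TRUE), collapse = "")),
         paste(sample(c("A", "C"), pad, TRUE), collapse = ""))
}

test_that("seed extraction slices mature positions 2-8 on the sense strand", {
  fi <- full_ingest()
  ann <- fi$ann
  # brute: recompute from the hairpin and annotation geometry by hand
  for (k in sample(nrow(ann$matures), 12)) {
    mt <- ann$matures[k, ]
    pre <- ann$precursors[ann$precursors$precursor_id == mt$precursor_id, ]
    hp <- ann$hairpins[[mt$precursor_id]]
    m_off <- if (pre$strand == "+") mt$start - pre$start else pre$end - mt$end
    expected <- substr(hp, m_off + 2, m_off + 8)
    sp <- extract_seed(ann, mt$mature_id)
    expect_equal(sp$seed7, expected)
    expect_equal(nchar(sp$seed7), 7)
    expect_equal(sp$variant_label, "reference")
  }
})

test_that("minus-strand seed equals the hand-computed reverse-complement read", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(path)
  ann <- read_mirna_gff(path)
  # hairpin for the minus precursor (genomic 300-380): sense strand is the
  # reverse complement of the genomic plus strand
  set.seed(55)
  genomic_plus <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  sense <- revcomp(genomic_plus, "dna")
  hp <- list("mir-plus" = dna_to_rna(paste(rep("A", 80), collapse = "")),
             "mir-minus" = dna_to_rna(sense))
  ann <- attach_hairpins(ann, unlist(hp))
  sp <- extract_seed(ann, "mir-minus-mat")
  # mature genomic (350, 372); sense 5' end at genomic 371; position p reads
  # the complement of genomic base 372 - p
  expected <- paste(vapply(2:8, function(p)
    complement_base(substr(genomic_plus, 372 - p - 300 + 1,
                           372 - p - 300 + 1)), character(1)), collapse = "")
  expect_equal(sp$seed7, dna_to_rna(expected))
})

test_that("SNP-altered seed differs at exactly the SNP position", {
  fi <- full_ingest()
  seed_calls <- fi$calls[fi$calls$compartment == "seed", ]
  for (i in seq_len(nrow(seed_calls))) {
    sc <- seed_calls[i, ]
    ref <- extract_seed(fi$ann, sc$mature_id)
    alt <- extract_seed(fi$ann, sc$mature_id, snp = sc)
    expect_equal(alt$variant_label, "snp_altered")
    d <- which(strsplit(ref$seed7, "")[[1]] != strsplit(alt$seed7, "")[[1]])
    expect_equal(d, sc$mature_position - 1)
  }
  # non-seed calls are rejected
  ns <- fi$calls[fi$calls$compartment == "mature_nonseed", ][1, ]
  expect_error(extract_seed(fi$ann, ns$mature_id, snp = ns), "2-8")
})

test_that("site rules match hand-constructed sites", {
  seed <- "AGCUUAU"  # mature positions 2-8
  # perfect site: revcomp of seed (DNA) = ATAAGCT, plus A for A1/8mer types;
  # C/G blockers stop one site type from embedding another
  utrs <- c(m8 = utr_with("CATAAGCTG"),   # positions 2-8, no A opposite 1
            a1 = utr_with("CTAAGCTAC"),   # positions 2-7 match + A
            mer8 = utr_with("CATAAGCTAC"),
            none = utr_with("CCCCCCCC"))
  expect_equal(match_targets(seed, utrs, "7mer_m8"), c("m8", "mer8"))
  expect_equal(match_targets(seed, utrs, "7mer_A1"), c("a1", "mer8"))
  expect_equal(match_targets(seed, utrs, "8mer"), "mer8")
  expect_equal(match_targets(seed, utrs, "any7plus"), c("a1", "m8", "mer8"))
  expect_true(all(c("a1", "m8", "mer8") %in%
                  match_targets(seed, utrs, "6mer")))
  # a UTR with no complementary 6-mer is never a target
  expect_false("none" %in% match_targets(seed, utrs, "6mer"))
})

test_that("site matching is position independent within the UTR", {
  seed <- "GGACUCA"
  site <- paste0(revcomp(rna_to_dna(seed), "dna"), "A")
  set.seed(31)
  bg <- paste(sample(c("A", "C"), 200, TRUE), collapse = "")
  for (at in c(1, 57, 120, 193)) {
    u <- bg
    substr(u, at, at + 7) <- site
    expect_equal(match_targets(seed, c(g = u)), "g")
  }
})

test_that("switch analysis obeys the Venn set identities", {
  sw <- switch_analysis(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(sw$common, c("b", "c"))
  expect_equal(sw$lost, "a")
  expect_equal(sw$gained, "d")
  # identity: no switching
  sw2 <- switch_analysis(c("x", "y"), c("y", "x"))
  expect_equal(sw2$lost, character(0))
  expect_equal(sw2$gained, character(0))
  # the arithmetic of a published Venn (890/542 split as 85 + 805 / 85 + 457)
  # is the structural invariant asserted for every analysis
  set.seed(19)
  for (r in 1:20) {
    ref <- sample(letters, sample(0:20, 1))
    alt <- sample(letters, sample(0:20, 1))
    sw <- switch_analysis(ref, alt)
    expect_equal(sw$counts[["n_ref"]],
                 sw$counts[["n_common"]] + sw$counts[["n_lost"]])
    expect_equal(sw$counts[["n_alt"]],
                 sw$counts[["n_common"]] + sw$counts[["n_gained"]])
  }
})

test_that("planted target sets are recovered exactly from the UTR set", {
  sr <- small_report()
  truth <- sr$sim$truth$targets
  expect_gt(length(sr$report$switches), 0)
  for (nm in names(sr$report$switches)) {
    sw <- sr$report$switches[[nm]]$switch
    tt <- truth[truth$mirna_id == nm, ]
    expect_setequal(sw$common, tt$gene[tt$set == "common"])
    expect_setequal(sw$lost, tt$gene[tt$set == "lost"])
    expect_setequal(sw$gained, tt$gene[tt$set == "gained"])
  }
})
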