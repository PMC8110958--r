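test_that("hypergeometric tail matches exact combinatorial arithmetic", {
  universe <- sprintf("g%02d", 1:20)
  ann <- list(T1 = universe[1:5])
  # all 5 annotated genes drawn in a target set of 5:
  # p = C(5,5) C(15,0) / C(20,5) = 1/15504
  rows <- hypergeom_enrich(universe[1:5], ann, universe)
  expect_equal(rows$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(rows$k, 5)
  # k = 0 is the certain event P(X >= 0) = 1
  rows0 <- hypergeom_enrich(universe[6:10], ann, universe)
  expect_equal(rows0$p_value, 1)
  # random configurations vs explicit summation, N <= 50
  set.seed(71)
  for (r in 1:40) {
    N <- sample(10:50, 1)
    uni <- sprintf("u%03d", seq_len(N))
    K <- sample(N, 1)
    n <- sample(N, 1)
    ann <- list(T = sample(uni, K))
    targ <- sample(uni, n)
    k <- length(intersect(targ, ann$T))
    p_direct <- sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
    rows <- hypergeom_enrich(targ, ann, uni)
    expect_equal(rows$p_value, p_direct, tolerance = 1e-9)
  }
})

test_that("enrichment table obeys its contracts", {
  set.seed(5)
  uni <- sprintf("g%03d", 1:100)
  ann <- lapply(stats::setNames(1:12, paste0("T", 1:12)),
                function(i) sample(uni, sample(5:40, 1)))
  ann$empty <- character(0)            # K = 0: skipped
  targ <- sample(uni, 25)
  rows <- hypergeom_enrich(targ, ann, uni)
  expect_false("empty" %in% rows$term_id)
  expect_true(all(rows$k <= pmin(rows$K, rows$n)))
  expect_true(all(rows$p_value > 0 & rows$p_value <= 1))
  expect_true(all(rows$fdr >= rows$p_value - 1e-12))
  # BH monotone in p rank
  expect_true(all(diff(rows$fdr[order(rows$p_value)]) >= -1e-12))
  expect_true(!is.unsorted(rows$p_value))
  # empty target set, and targets outside the universe
  expect_equal(nrow(hypergeom_enrich(character(0), ann, uni)), 0)
  expect_error(hypergeom_enrich(c("nope"), ann, uni), "universe")
})

test_that("null draws are calibrated: about 5% of terms reach p <= 0.05", {
  set.seed(2024)
  N <- 200; uni <- sprintf("g%03d", seq_len(N))
  ann <- lapply(stats::setNames(1:5, paste0("T", 1:5)),
                function(i) sample(uni, 40))
  reps <- 1000
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    targ <- sample(uni, 20)          # uniform draw: the null is true
    rows <- hypergeom_enrich(targ, ann, uni)
    hits <- hits + sum(rows$p_value <= 0.05)
    total <- total + nrow(rows)
  }
  rate <- hits / total
  # the discrete tail makes the test conservative: the exact rejection
  # probability at alpha = 0.05 for (N = 200, K = 40, n = 20) is the oracle
  k_grid <- 0:20
  pvals <- stats::phyper(k_grid - 1, 40, 160, 20, lower.tail = FALSE)
  exact_rate <- sum(stats::dhyper(k_grid, 40, 160, 20) * (pvals <= 0.05))
  expect_lte(exact_rate, 0.05)   # validity of the level
  se <- sqrt(exact_rate * (1 - exact_rate) / total)
  expect_lt(abs(rate - exact_rate), 4 * se)
})

test_that("comparison classifies terms and k is monotone for nested targets", {
  set.seed(9)
  uni <- sprintf("g%03d", 1:120)
  ann <- lapply(stats::setNames(1:10, paste0("T", 1:10)),
                function(i) sample(uni, sample(10:50, 1)))
  ref <- sample(uni, 40)
  alt <- sample(ref, 15)               # alt strictly inside ref
  e_ref <- hypergeom_enrich(ref, ann, uni)
  e_alt <- hypergeom_enrich(alt, ann, uni)
  cmp <- compare_enrichment(e_ref, e_alt, alpha = 1)  # keep every term
  both <- cmp[cmp$status == "both", ]
  expect_true(all(both$k_alt <= both$k_ref))
  # identical target sets: every term shared with k_ref = k_alt
  cmp2 <- compare_enrichment(e_ref, e_ref, alpha = 1)
  expect_true(all(cmp2$status == "both"))
  expect_equal(cmp2$k_ref, cmp2$k_alt)
  # mismatched universes are rejected
  e_bad <- hypergeom_enrich(sample(uni[1:60], 10), ann, uni[1:60])
  expect_error(compare_enrichment(e_ref, e_bad), "universe")
})

test_that("planted enrichment is detected on the right side", {
  sr <- small_report()
  truth <- sr$sim$truth$go
  nm <- truth$mirna_id[1]
  cmp <- sr$report$switches[[nm]]$comparison
  ref_term <- truth$term[truth$expected == "ref_enriched"]
  alt_term <- truth$term[truth$expected == "alt_only"]
  expect_true(ref_term %in% cmp$term_id[cmp$status != "alt_only"])
  expect_true(alt_term %in% cmp$term_id[cmp$status == "alt_only"])
  # shared significant terms engage fewer target genes after the seed SNP
  # whenever the altered target set is smaller
  e_ref <- sr$report$switches[[nm]]$enrich_ref
  expect_true(ref_term %in% e_ref$term_id[e_ref$fdr <= 0.05])
})
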