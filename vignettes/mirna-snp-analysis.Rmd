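---
title: "Methods: SNP impact analysis in microRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP impact analysis in microRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnp)
```

## The problem

Single nucleotide polymorphisms (SNPs) inside microRNA genes can perturb
gene regulation through two distinct routes. A SNP in the *seed* of the
mature miRNA (positions 2–8 from its 5′ end) rewrites the sequence that
selects target mRNAs, so the set of regulated genes can switch wholesale. A
SNP anywhere else in the hairpin precursor can change the thermodynamic
stability or the shape of the stem–loop, and thereby the efficiency of
Drosha/Dicer processing. `mirsnp` implements the downstream analysis of a
targeted-resequencing experiment over miRNA genes: it starts from a filtered
VCF, a miRBase-style GFF3 and the hairpin sequences, and quantifies both
routes, together with the population-genetic summaries such a survey
reports.

The package was built around a study design of 23 diploid animals
resequenced over 381 pig hairpin precursors, and its synthetic-data
generator emulates exactly that design; every statistic, however, is
computed from whatever inputs are supplied.

## Pipeline model

The pipeline is a deterministic function of its inputs and configuration,
organised in five stages:

1. **Ingest.** VCF records are kept iff the site depth satisfies
   `DP > 5`; genotypes are kept iff `GQ > 30` (failing genotypes become
   missing rather than discarding the site, because depth is a site-level
   property and quality a genotype-level one). Multi-allelic records are
   split into biallelic per-alt records, since every downstream statistic is
   defined per substitution. Coordinates are converted once, at the format
   boundary, to a single internal convention (0-based, half-open); VCF and
   GFF3 are 1-based inclusive, BED is already 0-based half-open.
2. **Compartment classification.** Each biallelic SNP inside a precursor is
   assigned to one of three compartments with priority seed →
   mature-beyond-seed → precursor-beyond-mature. The seed is mature
   positions 2–8, 1-based from the mature 5′ end; on minus-strand
   annotations position 1 is the genomically rightmost mature base, and the
   reported alleles are reverse-complemented onto the miRNA sense strand.
   Published tables of substitution types rarely state their strand
   convention, so the reporting strand is a configuration flag
   (`sense`, the default, or `vcf_ref`); transition/transversion totals are
   identical under both.
3. **Population statistics.** Minor allele frequency `min(p, 1 − p)` and
   observed heterozygosity from genotype dosages; inter-SNP distances as
   consecutive within-chromosome differences (cross-chromosome distances are
   physically undefined and excluded — note this convention when comparing
   with published genome-wide means); SNP density per kb of a supplied
   region set. Cohort means are reported with the population SD (divisor
   *n*), matching the "mean (± SD)" style of survey reports; a flag selects
   the sample SD.
4. **Hairpin stability impact.** Every classified SNP is substituted into
   its hairpin (a guard verifies the hairpin base equals the call's sense
   reference allele — this catches strand and offset bookkeeping errors) and
   both sequences are folded with the same engine.
   `ddg = MFE(alt) − MFE(ref)`, so positive values destabilise. Direction is
   called at `|ddg| ≥ 0.05` kcal/mol, i.e. the smallest change that prints
   as nonzero at one-decimal reporting; structural change is a base-pair
   set comparison of the two MFE structures. Precursors carrying several
   SNPs are flagged in the cohort summary, never silently dropped.
5. **Target switching and enrichment.** For each seed SNP, the reference and
   altered 7-nt seeds are matched against a 3′UTR set by canonical site
   rules (6mer, 7mer-m8, 7mer-A1, 8mer, or their `any7plus` union, the
   default stringency compromise). Gene-level deduplication applies:
   multiple sites in one UTR count once, and UTRs are scanned on the given
   strand only. The gained/lost/common sets satisfy
   `|ref| = |common| + |lost|` and `|alt| = |common| + |gained|` by
   construction. Each target set is then tested for GO-term
   over-representation with the upper-tail hypergeometric probability
   `P(X ≥ k)` and Benjamini–Hochberg FDR across terms, and the two runs are
   compared term-by-term.

Full hybridisation-energy target scoring (Miranda-style alignment) is a
deliberate non-goal: published target counts from consensus webservers
depend on the scorer and UTR database and cannot be regenerated from
sequence alone. The package's defined stage is canonical seed matching with
selectable stringency; the structural arithmetic and planted-truth recovery
are what the tests assert.

## The folding engines

RNA secondary-structure prediction is the one nontrivial numerical
component, so it is implemented three ways behind one contract
(dot-bracket structure plus energy):

* **`loop_energy`** (default) — Zuker-style dynamic programming over a
  nearest-neighbor free-energy model, implemented in C++. The model
  comprises a 6×6 stacking table over the canonical pairs (Watson–Crick
  values of the Xia et al. measurement series; wobble-involving stacks
  filled in by helix-strength class), hairpin/bulge/internal loop
  initiation tables with Jacobson–Stockmayer log extrapolation
  (`1.75·RT·ln(L/L_max)` at 37 °C), an internal-loop asymmetry penalty
  (0.6 kcal/mol per unpaired-length difference, capped at 3.0), and an
  affine multibranch model (closing 3.4, per branch 0.4, unpaired 0.0
  kcal/mol). Terminal-mismatch, dangle and special-loop bonuses are
  deliberately omitted: they improve absolute accuracy but are irrelevant
  to the sign-and-change questions the pipeline asks, and omitting them
  keeps the model exactly decomposable for the brute-force oracle.
  Interior loops are capped at 30 unpaired bases, the standard DP cutoff.
  The parameters ship as a plain-text table
  (`inst/extdata/loop_energy_params.tsv`) and can be replaced per call.
* **`nussinov`** — base-pair maximisation with pseudo-energy `−(pairs)`.
  A teaching engine and a second, independent optimum for the oracle tests.
* **`external`** — any exact MFE backend satisfying the contract; the
  shipped implementation shells out to `RNAfold` (ViennaRNA) when it is on
  the `PATH`. This is the engine to use when published RNAfold energies
  must be reproduced; the built-in engines promise correct optimisation of
  *their* model, not ViennaRNA's numbers.

Minimum hairpin loop is 3 nt everywhere. Lonely pairs are not forbidden
outright; in the energy model they are discouraged by loop penalties alone.
Co-optimal structures are resolved deterministically (shortest loops first,
then 5′-most branches), so `structure_changed` is reproducible
bit-for-bit.

**Validation.** Two independent routes check the DP: an exhaustive
enumerator of all pseudoknot-free structures (feasible to ~20 nt) and a
loop-decomposition energy evaluator written separately in R. The test suite
asserts, over hundreds of seeded random sequences, that the DP energy
equals the enumerated minimum and that the reported structure achieves its
reported energy; ΔΔG antisymmetry under allele swap is asserted on cohort
data. On designed stem–loops the `loop_energy` and `external` engines agree
on structure and closely on energy.

## The synthetic cohort

`simulate_cohort()` builds every input file from scratch, with
machine-readable truth tables. Its defaults *are* the emulated study
conditions, chosen once:

* 381 hairpin precursors on 19 chromosomes, half on the minus strand, stems
  of 26–41 pairs with up to 10% G·U wobbles and loops of 8–15 nt (A/C
  alphabet, so the loop cannot pair internally) — giving realistic hairpin
  lengths of ~60–97 nt and a total precursor territory near 30 kb; one
  22-nt mature per precursor on a random arm.
* 73 planted SNPs in 50 distinct precursors: 2 in seeds, 12 in matures
  beyond the seed, 59 elsewhere in the precursor; 60 of 73 are transitions
  (10 of the 14 mature-region SNPs, 50 of the 59 others), reproducing the
  transition-rich spectrum such surveys observe. Eight indel records and
  four low-depth decoys are added so the ingest filters and the SNP
  restriction are exercised (81 precursor variants in, 73 SNPs out), plus
  200 background SNPs in the capture flanks.
* Genotypes for 23 samples drawn under Hardy–Weinberg at a true alt-allele
  frequency uniform on [0.05, 0.5] (mean 0.275 — the realistic ascertained
  range for a resequencing panel; monomorphic draws are rejected because an
  uncalled variant would not appear in a VCF). Each genotype fails GQ with
  probability 0.02.
* Two stability classes are planted among the non-mature SNPs: mid-stem
  G→A substitutions that break a Watson–Crick G·C pair into a mismatch
  (expected: ΔΔG > 0 and a structural change) and loop substitutions within
  the A/C loop alphabet (expected: no change under `loop_energy`, whose
  loop terms are sequence-independent).
* 500 3′UTRs of 500 nt with 8mer sites planted for the two seed-SNP miRNAs
  (per miRNA: 20 genes with sites for both alleles, 40 reference-only, 25
  altered-only); UTRs are regenerated until they contain no accidental
  seed cores, so target-set recovery is exact, not statistical. A GO map of
  30 background terms plus one term loaded with reference targets and one
  with gained-only targets plants detectable enrichment on each side.

What the generator does **not** emulate: real miRBase sequence composition
and folding idiosyncrasies, linkage between nearby SNPs, read-level error
and coverage structure, genotype-caller artefacts, and UTR length/composition
biases. Passing the recovery tests therefore demonstrates that the
pipeline's bookkeeping (coordinates, strands, filters, set algebra,
estimators) is correct under known truth — not that any biological claim
about real data is reproduced.

## Numerical and design choices

* The site-depth filter reads `INFO/DP` (configurable), the natural reading
  of a site-level "total depth" filter; summed sample depth is an
  alternative some callers emit.
* The "nonzero ΔΔG" threshold of 0.05 kcal/mol follows from one-decimal
  energy reporting: 0.1 is the smallest printed nonzero change.
* The enrichment universe defaults to genes with at least one GO
  annotation (`annotated`); `all_utr_genes` is available because webserver
  universes differ and the choice shifts every p-value.
* Enrichment significance defaults to FDR ≤ 0.05 with a flag for raw
  p-values, since published figures label either.
* Degenerate inputs: a SNP with all genotypes missing is excluded from
  cohort means with a note; chromosomes with fewer than two variants
  contribute no distances; an empty compartment scope yields an explicit
  zero spectrum; a zero-length region is an error for densities.
* GO-graph propagation (the true-path rule) is out of scope; annotations
  are taken as given.

## Problem sizes in the test suite

The suite validates the DP against exhaustive enumeration on 200+ random
sequences of 10–20 nt, runs the full-scale cohort (381 precursors, 73
SNPs) through ingest/classification once, and uses a compact cohort
(60 precursors, 20 SNPs) for the end-to-end pipeline, chosen so the whole
suite exercises every stage at full fidelity while staying quick to run.
Estimator calibration uses 500–1000 Hardy–Weinberg or null-enrichment
replicates at the cohort size of 23.

## A worked example

```{r example, eval = FALSE}
library(mirsnp)

sim <- simulate_cohort(sim_config(seed = 1))
cfg <- pipeline_config(vcf = sim$paths$vcf, gff = sim$paths$gff,
                       hairpin_fasta = sim$paths$hairpin_fasta,
                       utr_fasta = sim$paths$utr_fasta,
                       go_tsv = sim$paths$go_tsv,
                       capture_bed = sim$paths$capture_bed)
report <- run_pipeline(cfg)
print(report)
```

## Known limitations

* The built-in energy model is simplified; absolute MFE values differ from
  ViennaRNA's (signs and structural calls agree on designed stems, and the
  `external` engine exists for exact reproduction).
* Canonical seed matching ignores 3′-supplementary pairing, site
  accessibility and conservation; counts are not comparable with consensus
  webserver outputs.
* Distances and densities follow the stated conventions; comparing against
  reports that used other conventions (e.g. all-pairs distances) requires
  care.
* isomiRs, alternative Drosha/Dicer cleavage and pri-miRNA flanks are not
  modelled.
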