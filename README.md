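# mirsnp

Downstream analysis of SNPs called in microRNA genes, for
variant-calling / population-genetics workflows that resequence miRNA loci
(targeted capture panels or WGS subsets). Starting from a filtered VCF, a
miRBase-dialect GFF3 and the hairpin FASTA, the package answers the two
questions such surveys ask:

1. **Where do the SNPs fall and what do they look like?** Each biallelic
   SNP inside a precursor is placed in the compartment hierarchy — seed
   (mature positions 2–8), mature beyond the seed, precursor beyond the
   mature — with strand-correct sense alleles, the 12-class substitution
   spectrum with transition/transversion fractions, per-SNP minor allele
   frequency `MAF = min(p, 1 − p)` and observed heterozygosity, inter-SNP
   distances and SNP density per kb.
2. **What do the SNPs do?** Every precursor is folded with and without its
   SNP and the stability change `ΔΔG = MFE(alt) − MFE(ref)` (kcal/mol,
   positive = destabilising) is classified, together with a base-pair-level
   structural-change call. For seed SNPs, reference and altered 7-nt seeds
   are matched against a 3′UTR set by canonical site rules (6mer, 7mer-m8,
   7mer-A1, 8mer), the target switch is quantified as common/lost/gained
   sets, and each target set is tested for GO over-representation with the
   upper-tail hypergeometric test `P(X ≥ k)` for `k` annotated targets among
   `n` drawn from a universe of `N` with `K` annotated, under
   Benjamini–Hochberg FDR.

Folding is provided by three engines behind one contract: a Zuker-style
nearest-neighbor dynamic program implemented in C++ (`loop_energy`, the
default, with a shipped Turner-style parameter table), a Nussinov base-pair
maximiser (`nussinov`), and a pluggable exact backend (`external`, using
`RNAfold` when available). A fully self-contained synthetic-cohort
generator emits every input format with machine-readable ground truth, so
the whole pipeline is testable offline.

## Worked example

```r
library(mirsnp)

sim <- simulate_cohort(sim_config(seed = 1))   # 381 precursors, 23 samples
cfg <- pipeline_config(vcf = sim$paths$vcf, gff = sim$paths$gff,
                       hairpin_fasta = sim$paths$hairpin_fasta,
                       utr_fasta = sim$paths$utr_fasta,
                       go_tsv = sim$paths$go_tsv,
                       capture_bed = sim$paths$capture_bed)
report <- run_pipeline(cfg)
print(report)
```

```
mirsnp pipeline report
  variants passing filters: 281 
  variants in precursors:   81 
  SNPs in precursors:       73 (in 50 unique precursors, 13.1%) 
  compartments:  seed=2 mature_nonseed=12 precursor_nonmature=59  (2.7% / 16.4% / 80.8%)
  transitions: 82.2 % (precursor scope), 71.4 % (mature scope)
  mean MAF 0.258 (+/- 0.133), mean het 0.36
  ddG: 54 nonzero (49 up, 5 down), mean |ddG| 3.54, 30 structure changes
  sim-mir-095-3p: n_ref=60 n_alt=45 n_common=20 n_lost=40 n_gained=25
  sim-mir-303-5p: n_ref=60 n_alt=45 n_common=20 n_lost=40 n_gained=25
```

Reading the output: of 281 variants passing the hard filters
(`DP > 5`, genotype `GQ > 30`), 81 fall inside hairpin precursors and 73
are biallelic SNPs, hitting 50 distinct precursors (13.1% of the 381
annotated). The compartment split and the transition-dominated spectrum are
the classic negative-selection gradient: the seed carries the fewest
variants. 54 SNPs shift the hairpin's minimum free energy (49 destabilise),
and 30 change the minimum-energy structure. For each of the two seed SNPs,
the predicted target set switches: e.g. 60 reference targets split into 20
retained and 40 lost, with 25 gained — and the per-side GO enrichment
tables (in `report$switches`) show which processes move with them.

Single stages are exported (`read_vcf()`, `classify_variants()`,
`substitution_spectrum()`, `snp_summary()`, `fold_mfe()`, `ddg_analysis()`,
`extract_seed()`, `match_targets()`, `hypergeom_enrich()`, ...), and a thin
CLI wraps the two entry points:

```sh
inst/exec/mirsnp simulate --seed 1 --out cohort/
inst/exec/mirsnp run --vcf cohort/variants.vcf --gff cohort/mirna.gff3 \
    --hairpin-fasta cohort/hairpin.fa --out results/
```

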