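Package: mirsnp
Title: SNP Annotation, Hairpin Stability and Target Switching for microRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of single nucleotide polymorphisms (SNPs)
    called in microRNA genes. Places SNPs into the precursor/mature/seed
    compartment hierarchy with strand-correct substitution typing, computes
    population summaries (minor allele frequency, observed heterozygosity,
    inter-SNP distances, densities), folds reference and SNP-altered hairpin
    precursors to quantify minimum-free-energy changes (delta-delta-G) and
    secondary-structure impact, predicts target-gene switching for seed SNPs
    by canonical seed matching over 3'UTRs, and compares hypergeometric GO
    enrichment between reference and SNP-altered target sets. Includes a
    fully self-contained synthetic-cohort generator with machine-readable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    rtracklayer,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
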