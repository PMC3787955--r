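Package: cnvrmap
Title: Consensus Copy Number Variable Region Mapping from SNP Array CNV Calls
Version: 0.1.0
Authors@R: person("CNVR", "Maintainers", email = "maintainers@cnvrmap.org", role = c("aut", "cre"))
Description: Builds consensus copy number variable region (CNVR) maps from
    per-algorithm CNV call sets derived from SNP genotyping arrays. Provides
    SNP genotype quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), per-algorithm CNV filtering and aggregation into
    CNVRs, multi-algorithm consensus construction, breed/generation cohort
    comparison, interval-overlap annotation against genes, QTLs and GWAS
    SNPs, qPCR 2^-ddCt relative-quantification validation scoring, and a
    fully seeded synthetic-data generator emulating a multi-caller SNP-chip
    CNV study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
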