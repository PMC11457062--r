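Package: pikescan
Title: Population Genomics and Sex-Linked-Region Detection for Low-Diversity Fish Cohorts
Version: 0.1.0
Authors@R:
    person("pikescan", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a whole-genome-resequencing
    population-genomics workflow for northern pike (Esox lucius) and similar
    low-diversity fish cohorts: a GATK/VCFtools-style hard-filter cascade with
    a per-step retention report, per-individual and per-population diversity
    statistics (genotype tallies, observed heterozygosity, private alleles,
    fixed differences, windowed Tajima's D, identity-by-state distances),
    chromosome-window polymorphism scans with Tukey outlier detection,
    discriminant analysis of principal components (DAPC) built from first
    principles, and three complementary detectors for XY sex-linked regions
    (sex-specific 31-mers from raw reads, genotype-pattern/DAPC screens, and
    read-depth ratio presence/absence genotyping of a male-limited scaffold).
    A fully seeded synthetic-cohort module generates reference genomes,
    multi-population diploid VCFs with a planted sex region and male-only
    insert contig, per-sample reads, and a machine-readable truth file for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
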