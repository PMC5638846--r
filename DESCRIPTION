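Package: focalGain
Title: Focal Single-Copy Gain Detection and Driver Analysis for Targeted Tumour Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects focal single-copy duplications (such as tandem duplications of
    the brachyury/T locus in chordoma) from targeted capture sequencing by fusing
    three evidence channels: binned fragment-start coverage with exact Poisson
    confidence intervals, B-allele frequencies of heterozygous SNPs, and
    statistically inferred haplotype blocks. Includes a rule engine for calling
    driver mutations (truncating events in recessive cancer genes, oncogene
    hotspots, focal amplifications and homozygous deletions), cohort-level
    statistics (one-sided Fisher enrichment of truncating mutations with
    hypermutator exclusion, a permutation test on indel frame composition, and a
    locus-mutability comparison with multiple-testing correction), and a seeded
    synthetic-data generator that emulates tumour targeted-capture data for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'caller.R'
    'cohortStats.R'
    'coverage.R'
    'drivers.R'
    'focalGain-package.R'
    'io.R'
    'phasing.R'
    'plots.R'
    'simulate.R'
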