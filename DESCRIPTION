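Package: herdscan
Title: Population-Genomic Diversity, Inbreeding and Selection-Signature Scans for Multi-Breed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing genomic diversity, inbreeding,
    relatedness and selection signatures in multi-population resequencing
    cohorts such as cattle breed panels. Implements Hudson's F_ST as a ratio
    of averages (genome-wide and in windows with top-fraction region
    extraction), windowed nucleotide diversity, observed and expected
    heterozygosity with the excess-of-homozygosity inbreeding coefficient
    F_Hom, a two-state hidden Markov model caller for runs of homozygosity
    with F_RoH length classes and population-level RoH islands, the
    cross-population extended haplotype homozygosity scan (XP-EHH), UPGMA
    phylogenies from Manhattan genotype distances, VanRaden genomic
    relationship matrices with greedy least-related subset selection, and f3
    admixture statistics with block-jackknife errors. A Balding-Nichols
    cohort simulator with plantable autozygous segments and haplotype sweeps
    provides ground truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
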