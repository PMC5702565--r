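Package: ppromburden
Title: Rare-Variant Burden, Consequence and Ancestry Analysis for PPROM
    Candidate Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Candidate-gene rare-variant analysis for preterm premature
    rupture of membranes (PPROM) case-control cohorts. Classifies coding
    consequences (nonsense, frameshift, start-loss) on transcript models,
    applies damaging-variant inclusion rules with PolyPhen2/SIFT consensus
    labels, estimates per-group allele frequencies from diploid genotype
    matrices with missing-call exclusion, tests across-loci case/control
    overrepresentation with a paired Wilcoxon signed-rank statistic under a
    sign-flip permutation null (with an exact enumeration oracle), estimates
    individual admixture proportions by maximum likelihood from
    ancestry-informative markers, and reproduces cohort demographic
    comparisons. Includes a seeded synthetic-cohort generator and VCF input
    and output for all genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
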