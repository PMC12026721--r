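Package: tgscore
Title: Total Genetic Score Profiling for Elite Point-Fighting Athletes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Polygenic profiling of combat-sport athletes from three
    performance-enhancing polymorphisms (ACE I/D, PPARalpha C/G, CKM A/G).
    Implements the power-oriented genotype score and Total Genetic Score
    (TGS = GS * 100/6) with metabolism and orientation classification,
    PCR-RFLP genotype calling from restriction-fragment lengths with
    tolerance-based matching, cohort genotype and allele frequency tables,
    a biallelic Hardy-Weinberg exact test, training-volume summaries, and a
    seeded synthetic-cohort generator reproducing the statistical structure
    of a 24-athlete elite point-fighting cohort so the whole pipeline runs
    without external data. Includes CSV input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'loci.R'
    'rflp.R'
    'scoring.R'
    'frequencies.R'
    'cohort.R'
    'synthetic.R'
    'io.R'
    'report.R'
    'cli.R'
    'tgscore-package.R'
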