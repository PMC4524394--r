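Package: ssrmarkers
Title: Microsatellite Marker Development and Codominant-Marker Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for developing simple sequence repeat (SSR) markers from
    genomic reads and analysing genetic diversity with codominant genotype
    data. Includes Class I SSR mining (di-/tri-/tetra-nucleotide motifs),
    lightweight primer-pair selection with nearest-neighbor melting
    temperatures, an in silico PCR engine with 3'-anchored k-mer binding-site
    search, marker validation verdicts and cross-taxon transferability rates,
    per-locus and per-population diversity statistics (PIC, heterozygosities,
    rarefied and private allelic richness), distance-based AMOVA with PhiPT
    permutation tests, Nei genetic distances with UPGMA tree construction, and
    non-model-based population structure inference (sequential K-means with
    BIC selection and discriminant analysis of principal components).
    Seeded synthetic-data generators provide reads with planted SSRs,
    polymorphic template genome pairs, and structured diploid genotype
    matrices with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
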