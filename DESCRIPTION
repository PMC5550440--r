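Package: hetgwas
Title: Resampling GWAS and Combining-Ability Analysis of Heterosis in
    Partial-Diallel Hybrid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide dissection of heterosis in partial-diallel
    hybrid crop populations, built around two-line hybrid rice designs in
    which male-sterile maternal lines are crossed to recombinant-inbred
    restorer lines. Derives heterosis phenotypes (better-paternal values,
    mid-parent values, general and specific combining abilities), runs a
    forward-selection resampling genome-wide association scan with a
    kinship-aware mixed-model score test under four inheritance codings
    (additive, dominance, recessive, overdominance), aggregates resample
    model inclusion probabilities (RMIP), merges signals into QTLs with
    haplotype-block intervals, classifies QTL genotype-class structure and
    dominance degree (d/a), traces superior-allele parental provenance, and
    scans parental groups for selection with windowed Tajima's D. A bundled
    diallel simulator with known QTL architecture makes every stage testable
    without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    optparse
Config/testthat/edition: 3
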