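Package: ccpower
Title: Simulation-Based QTL Mapping Power Analysis for Eight-Founder
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the power to detect quantitative trait loci (QTL) in
    multiparental recombinant inbred panels such as the Collaborative Cross,
    using simulation on founder-haplotype mosaic genomes.  Phenotypes are
    simulated from a single QTL with a configurable allelic series (a
    partition of the eight founder haplotypes into functional alleles),
    polygenic strain effects, and noise; QTL are mapped by Haley-Knott
    regression of strain means on founder haplotype dosages, with genome-wide
    significance thresholds calibrated by permutation and a generalized
    extreme value fit.  The package summarises power, false positive rate,
    location error and effect-size inflation (the Beavis effect), supports
    structured-null experiments with a realized kinship matrix, and ships a
    synthetic-genome generator so the whole pipeline runs without external
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
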