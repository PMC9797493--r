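Package: MosaicLOH
Title: Read-Depth Dosage, qPCR and Screening Analysis of Mosaic
    Heterozygous Deletions in Irradiated M1 Plants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects megabase-scale heterozygous deletions in mosaic plant
    tissue (e.g. seed-coat-enriched DNA from irradiated Arabidopsis M1
    plants) from binned sequencing coverage via relative read depth (RRD),
    estimates the mutant cell fraction from the depth depression, quantifies
    locus copy ratios from qPCR cycle thresholds by the comparative Ct
    method, performs exact binomial tests on mutant-class screening counts
    with gene-length-weighted nulls, and fits single-hit multitarget
    radiation survival curves. A synthetic-data generator emulating mosaic
    seed-coat sequencing, qPCR, screening and dose-survival experiments
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    minpack.lm,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: CopyNumberVariation, Coverage, Sequencing, qPCR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
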