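Package: barseqfit
Title: Barcoded Mutant-Pool Fitness, Expression Profiling, and Their
    Integration for Carbon-Catabolism Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying carbon-catabolism genes by
    combining barcoded insertional mutant-pool fitness profiling (BarSeq /
    RB-TDNA-seq) with bulk RNA-seq differential expression, as applied to
    d-galacturonic acid metabolism in the oleaginous yeast Rhodosporidium
    toruloides. Provides barcode extraction and counting from FASTQ,
    log2-ratio strain fitness scores with depth-weighted gene aggregation
    and a variance-floor T-statistic, FPKM computation with ANOVA-based
    differential testing and correlation-based hierarchical clustering, the
    joint expression-by-fitness quadrant filter for candidate gene calls,
    Michaelis-Menten kinetics utilities for the pathway enzymes, and a
    synthetic-data generator with known ground truth so every stage is
    testable without the deposited sequencing accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
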