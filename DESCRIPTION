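Package: cannamark
Title: Genetic Markers Discriminating Drug-Type from Fiber-Type Cannabis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating drug-type (marijuana)
    from fiber-type (hemp) Cannabis sativa using SNP and indel markers in the
    THCAS and CBDAS coding sequences. Provides variant discovery against CDS
    references, per-locus Firth penalized-likelihood association scans with
    Benjamini-Hochberg false-discovery-rate control, consensus-allele
    discriminant scores with AUC-optimized weights and bootstrap evaluation,
    Gower-distance multidimensional-scaling and entropy summaries of genetic
    variation, protein-consequence prediction (synonymous/non-synonymous
    calls, side-chain impact grading, frameshift and premature-stop
    detection), THC/CBD chemotype arithmetic, and a synthetic-panel generator
    so the whole analysis is exercisable end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
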