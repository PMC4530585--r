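Package: axispattern
Title: Positional Analysis of Meiotic Axis-Protein and Cohesin ChIP-Seq Signals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the chromosomal positioning of meiotic
    axis proteins (Red1/Hop1) and cohesin (Rec8) from ChIP-seq data in
    budding yeast: read extension and fragment-size estimation, median and
    background-ratio normalization, Poisson local-lambda peak calling with
    summit definition and gene-feature classification, gene-pair oriented
    meta-profiles (metagene, intergenic-midpoint, transcript-end aligned,
    overlap-ranked matrices, expression strata and delta-RPKM quantile
    skew), chromosome-scale density statistics, centromere-aligned doublet
    profiles, and GAN-repeat motif scanning.  A synthetic-data module
    encodes a transcription-driven cohesin-sliding occupancy model and
    emits read-level ChIP/input/untagged data with exported ground truth,
    so every analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
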