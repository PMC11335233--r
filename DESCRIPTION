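Package: loop4c
Title: 4C-Seq Chromatin Interaction Calling with Distance-Decay Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for circular chromosome conformation capture
    sequencing (4C-seq) viewpoint analysis: in-silico restriction
    fragmentation of a genome by a primary six-cutter and secondary
    four-cutter, per-fragment read counting and RPKM normalization with
    bait-proximal exclusion, monotone distance-decay modelling with
    per-fragment z-scores and Benjamini-Hochberg FDR for replicate-
    concordant cis-interaction calling, diet-differential contact
    detection by average z-score ratio, hidden-Markov-model segmentation
    of smoothed trans-chromosomal signal into interaction domains,
    TAD-overlap annotation with a tolerance distance, and log2-ratio
    comparison of normalized Hi-C contact matrices. Includes a
    negative-binomial synthetic-data generator with planted cis and
    trans interactions for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
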