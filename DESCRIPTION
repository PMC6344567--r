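Package: fusionneo
Title: Fusion Transcript Validation, Neoepitope Prediction and Fusion-Fraction Metrics from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates gene-fusion candidates called from RNA-seq (deFuse-style
    tables) against de novo assembled transcripts (Trinity-style contigs) by
    local alignment of the junction-flanking window, requiring the alignment
    to span the breakpoint. Classifies fusions as inter-chromosomal,
    intra-chromosomal or transcription-induced chimeras (read-through of
    neighbouring genes), predicts open reading frames on fusion contigs,
    characterizes the fusion protein (in-frame versus frameshift, novel
    C-terminal tail), tiles 8-11-mer neoepitope candidates around the fusion
    point for MHC class I binding prediction, and computes per-sample
    genomic-instability metrics: the RNA-seq fusion fraction (validated-fusion
    span counts per 10 million mapped paired reads) with Kaplan-Meier and
    log-rank survival stratification, and the exon/intron coverage ratio that
    quantifies read-through chimera abundance. Ships a deterministic synthetic
    fixture generator with planted ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
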