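Package: quadclip
Title: Conversion-Aware PAR-CLIP Analysis for G-Quadruplex-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of PAR-CLIP experiments on RNA
    G-quadruplex (rG4) binding proteins such as DEAH-box helicases.
    Calls binding-site clusters from transcript-space reads carrying
    diagnostic T-to-C conversions, scores per-gene occupancy as
    normalized crosslinked reads per million (NXPM), computes k-mer
    Z-score enrichment against a composition-preserving shuffled
    background, scans for canonical rG4 motifs, builds metagene profiles
    around start and stop codons with a randomized-placement null, and
    integrates RNA-seq and Ribo-seq count matrices into occupancy-binned
    fold-change and translational-efficiency comparisons with
    Kolmogorov-Smirnov statistics, plus exponential mRNA decay fits and
    corrected total cell fluorescence. A seeded synthetic-data generator
    produces transcriptomes with planted G4 sites, crosslink reads, and
    wild-type versus knockout count matrices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
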