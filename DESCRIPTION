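Package: zflipon
Title: Z-Flipon Discovery with Dinucleotide Energetics and a 6-mer Transformer Segmenter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for locating Z-flipons, genomic sequences that can flip
    from right-handed B-DNA into the left-handed Z conformation under
    torsional stress. Provides a thermodynamic Z-propensity scorer built on
    per-dinucleotide B-to-Z transition costs with a B-Z junction penalty, a
    from-scratch transformer encoder that classifies 6-mer tokens into Z /
    non-Z at nucleotide resolution with stratified cross-validated ensembling,
    in-silico saturation mutagenesis effect maps, attention-map
    interpretability, and downstream interval, genomic-feature, repeat-family
    and haplotype analytics. A seeded synthetic-genome generator with
    energetics-derived ground truth makes the whole pipeline testable on a
    desktop without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
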