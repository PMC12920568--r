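Package: orf2pep
Title: Gene Calling and Functional Peptide Screening with Fused Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage workflow for mining candidate therapeutic peptides
    from prokaryotic and metagenomic DNA. Stage one enumerates open reading
    frames in all six frames, encodes each candidate as a fused vector of
    one-hot sequence context and handcrafted coding statistics (monocodon and
    dicodon usage, a translation-initiation-site score, length, GC content and
    base composition), and scores coding potential with a convolutional
    network followed by a multi-head self-attention encoder; overlapping
    predictions are resolved greedily. Stage two translates the retained genes
    and classifies the peptides as anticancer or antimicrobial candidates with
    a dual-channel convolutional/bidirectional-LSTM model over residue
    embeddings, then profiles eight physicochemical properties (GRAVY,
    molecular weight, aromaticity, instability index, isoelectric point, net
    charge, Boman index, tryptophan content). Includes seeded simulators for
    genomes with embedded codon-biased genes and compositionally separable
    peptide sets, so the whole pipeline trains and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
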