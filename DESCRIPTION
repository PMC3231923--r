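Package: piluscan
Title: Detection and Characterization of Sortase-Dependent Pilus Gene
    Clusters in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates sortase-dependent pilus gene clusters in
    Gram-positive bacterial genomes, with a focus on bifidobacteria.
    Pilin subunit genes are recognized by position-specific scoring
    matrices for the LPXTG cell wall sorting signal, the pilin motif and
    the E-box, combined with a Sec secretion-signal heuristic and a
    class C sortase check. Candidate loci are assembled from classified
    genes, screened for flanking mobile elements, 3' rho-independent
    terminator hairpins (nearest-neighbor free energy), slippage
    pseudogenes, and horizontal-gene-transfer signals (G+C deviation,
    relative synonymous codon usage distance). Companion tools compute
    Kimura two-parameter distances and neighbour-joining trees with
    bootstrap supports for pilin gene alignments, efficiency-corrected
    delta-delta-Ct qPCR fold changes, and fully seeded synthetic genomes
    with planted pilus operons for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
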