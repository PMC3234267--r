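Package: sinexapt
Title: Detection of Shared Transcription-Factor Binding Sites in Exapted SINE Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the exaptation of short interspersed nuclear
    element (SINE) copies into conserved non-coding enhancers. Diverged,
    5'-truncated copies of a repeat family are aligned to the family consensus
    with a truncation-tolerant semi-global dynamic program, scanned on both
    strands with position weight matrices built from TRANSFAC-style count
    matrices, and every motif hit is projected into consensus coordinates with
    strand resolution. Cross-locus shared binding sites are then detected by
    single-linkage clustering of projected positions, tested for concentration
    in annotated consensus domains by permutation, and orthologous locus sets
    are analysed with exact (exhaustive or branch-and-bound) Fitch maximum
    parsimony with outgroup rooting. A synthetic SINE-family generator with
    full ground truth (divergence, indels, 5'-truncation, embedded motif
    instances, tree-structured orthologs) makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
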