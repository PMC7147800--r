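Package: nacprofiler
Title: Genome-Scale Characterization of NAC Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome-scale characterization of NAC (NAM/ATAF/CUC)
    transcription factors from protein and coding sequences: a PROSITE-style
    motif engine with the NAC consensus-motif catalog for domain confirmation
    and chimeric-architecture flags, physicochemical profiling (molecular
    weight, isoelectric point by bisection, hydropathy-based transmembrane
    segment calling), a two-state hidden Markov model nuclear localization
    signal detector with Viterbi and posterior decoding, an NLS taxonomy
    (monopartite class I/II, bipartite, non-canonical class III/IV,
    multipartite) with linker-collapsed signature censuses, codon usage and
    relative synonymous codon usage (RSCU), Tamura-Nei (TN93) substitution
    pattern estimation with transition/transversion summaries,
    neighbour-joining trees with bootstrap support, and gene-tree/species-tree
    LCA reconciliation for duplication and loss counting. Seeded synthetic-data
    generators provide proteomes, codon-biased CDS, TN93-evolved alignments,
    and gene families with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
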