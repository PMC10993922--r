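Package: boseq
Title: Single-Nucleotide m7G Detection in tRNA from Chemical-Cleavage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of borohydride/aniline chemical-cleavage sequencing
    (Bo-Seq) libraries for single-nucleotide detection of internal
    N7-methylguanosine (m7G) in tRNA. Builds a CCA-tailed, identity-collapsed
    mature-tRNA mapping reference with genomic flank intervals for pre-tRNA
    filtering, tabulates per-position fragment start sites in treated and
    untreated libraries, computes log2 cleavage scores and calls
    guanosine-restricted candidate m7G sites, and projects calls onto
    isoacceptor canonical coordinates via multiple alignments. Includes a
    chemistry-aware read simulator with ground-truth logs so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
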