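Package: tinyte
Title: Dynamic-Boundary Detection of Full-Length Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo identification of full-length transposable elements (TEs)
    in genome assemblies by fault-tolerant mapping expansion (FMEA): fragmented
    local-alignment hits are chained across indels and nested insertions into
    coarse candidates, fine boundaries are recovered from structural signatures
    (target-site duplications, terminal inverted repeats, Helitron hairpin and
    CTRR termini, polyA tails, long terminal repeats), false positives are
    removed by tandem-repeat and multiple-sequence-alignment homology-boundary
    filters with dynamic boundary adjustment, nested elements are unwrapped,
    and a classified consensus library is produced.  Includes a synthetic
    genome simulator with planted, degraded, nested TE families and full
    ground truth, library benchmarking statistics (reciprocal-coverage
    sensitivity/precision/FDR/F1 and Perfect/Good/Present categories),
    terminal sequence-logo matrices, and LTR insertion-time dating.
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
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb, blastx), MAFFT
Config/testthat/edition: 3
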