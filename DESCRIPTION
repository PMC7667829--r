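Package: transductr
Title: Detection of DNA Transduction Signatures from Paired Metagenome
    and Virome Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies coverage signatures of DNA transduction
    from paired read-coverage tracks: a whole-community metagenome and an
    ultra-purified virus-like particle (VLP) fraction mapped onto the same
    contigs. Builds binned, normalized coverage tracks from alignments or
    depth files; segments VLP coverage with change-point analysis; classifies
    contigs into prophage/island induction, specialized, lateral, generalized
    (headful) and gene-transfer-agent-like transduction modes; estimates
    transducing-particle frequencies, pac-site positions and headful sizes;
    and screens candidate contigs for cellular-DNA contamination with a
    normalized-coverage rank comparison. Includes a mechanistic simulator of
    DNA packaging into VLPs that provides ground-truthed synthetic inputs for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
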