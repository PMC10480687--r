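Package: RepeatLift
Title: Mapping ChIP-seq Signal and Sequences Between Genomic and Repeat
    Consensus Coordinates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of ChIP-seq/ChIP-exo signal
    inside transposable elements and other repeats. Compiles UCSC-style
    liftOver chains directly from RepeatMasker alignment (.align) files so
    that repeat coordinates stay consistent with the consensus sequences,
    lifts reads from genomic coordinates onto repeat consensus coordinates
    ("liftIn") with multi-mapping-safe deduplication, computes windowed
    Fold Change over Control (F.C.C.) tracks normalized by library size,
    extracts the genomic sequences underlying any consensus locus from all
    repeat instances ("liftOut"), builds position frequency matrices from
    the extracted sites, and predicts per-site binding energies with an
    additive position energy matrix. Includes a ground-truthed simulator of
    repeat genomes and ChIP/input read sets for validation.
License: GPL-3
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
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Epigenetics, ChIPSeq, Coverage, Alignment, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
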