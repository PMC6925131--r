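Package: breakome
Title: Nucleotide-Resolution Mapping and Profiling of Single-Strand DNA Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls single-strand DNA breaks (SSBs) at single-base resolution
    from polyA-tailed sequencing libraries produced with either a paired-end
    Illumina-style chemistry or a single-molecule (SMS-style) chemistry, and
    profiles the resulting "breakome". Implements the chemistry-specific read
    structure and quality filters, unique-alignment ingest from SAM/BAM, the
    strand-aware single-base break-coordinate rules (including the one-base
    fill-and-lock extension), the oligo-dT internal-priming filter, untailed
    control subtraction, repeat masking and double-strand-break pairing.
    A statistics suite covers interval enrichment by exact binomial test,
    template-strand asymmetry, replication-timing and nucleosome signal
    comparisons, variant-window overlap, conservation-score profiles,
    per-base site profiles and normalized scores, detection-sensitivity and
    library-complexity curves, hotspot partitioning and hypergeometric
    gene-set enrichment. Sample-level profiling builds per-gene-strand
    break-density matrices, PCA embeddings, eight-feature sample vectors and
    logistic/linear age models. A seeded simulator generates synthetic
    genomes, planted breaks and reads for both chemistries (with
    internal-priming artifacts and untailed controls) so the whole pipeline
    is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    pROC,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
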