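Package: trendsig
Title: Three-State Disease-Progression Gene Signatures and Regulome
    Integration for Thyroid Cancer Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives three-state (normal / differentiated / anaplastic
    thyroid carcinoma) disease-progression gene signatures from multi-study
    log2 expression matrices: per-comparison differential statistics with
    Benjamini-Hochberg correction, monotone trend classification with
    discordant-probe exclusion, a standardized fold-change (sFC) statistic
    with explicit S1/S2/S3 cutoffs, and extraction of the disease gene
    module as the largest connected component of the signature genes in a
    protein-protein interaction network. Companion stages normalize
    NanoString-style count panels for signature validation, filter ChIP-seq
    peaks to a replicate consensus, assign peaks to genes by a TSS window,
    and intersect knockdown differential-expression tables with ChIP
    targets into a core transcription-factor program. A synthetic-data
    generator with planted truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    limma,
    BiocGenerics,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
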