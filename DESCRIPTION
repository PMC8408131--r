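Package: floramark
Title: Tissue-Specific Marker Gene Discovery from Multi-Tissue Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers floral whorl/tissue-specific marker genes from a
    multi-tissue bulk RNA-seq expression matrix. Implements the tau
    tissue-specificity index with per-tissue expression fractions, BIN
    profiles and a composite marker score; a signed weighted gene
    co-expression network (soft-threshold selection by scale-free fit,
    topological overlap, average-linkage module detection, eigengenes,
    module membership and module-trait association); intersection of the
    two approaches into key hub genes; housekeeping-gene calling;
    hypergeometric gene-set enrichment; and discriminative k-mer promoter
    motif discovery with position-weight-matrix library matching. A
    synthetic-data module generates expression matrices, promoter sets and
    gene-set collections with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    limma,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    rtracklayer
Config/testthat/edition: 3
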