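Package: cnmfr
Title: Consensus Non-Negative Matrix Factorization for Gene Expression Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers gene expression programs (GEPs) of cell-type identity and
    cellular activity from single-cell RNA-Seq count matrices by consensus
    non-negative matrix factorization (cNMF): many independently seeded NMF
    replicates are run on a variance-scaled matrix of over-dispersed genes,
    outlier components are removed by a K-nearest-neighbour distance filter,
    the surviving components are clustered and median-merged into consensus
    spectra, and per-cell usages and transcripts-per-million-scale spectra
    are refit by non-negative least squares. Includes a Splatter-style
    single-cell count simulator with an activity program and doublets,
    diagnostics for choosing the number of components, marker-gene
    regression and gene-set enrichment, and a benchmarking harness with
    consensus-ICA and ground-truth-clustering baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
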