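Package: discpair
Title: Paired Single-Cell and Single-Nuclei RNA-Seq Comparison Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the side-by-side analysis of droplet-based single-cell
    and single-nuclei RNA-seq experiments on the same tissue. Provides readers
    and writers for 10x-style sparse UMI count matrices, a synthetic generator
    of paired cell/nuclei datasets with planted cell identities and
    modality-specific artefacts (mitochondrial failure, ribosomal and
    heat-shock load), modality-aware quality control, depth normalization and
    highly-variable-gene selection, shared-nearest-neighbor graph clustering,
    one-vs-rest Wilcoxon marker detection with Benjamini-Hochberg adjustment,
    marker-matrix cluster annotation with dual-identity tie rules, cluster
    merging, a simple joint integration of both modalities, and the
    cross-modality comparison statistics: corrected contribution proportions,
    variable-gene overlaps, per-identity differential-expression overlap, and
    barcode-tracked cluster transitions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
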