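Package: rabscreen
Title: Rabbit B-Cell Antibody Repertoire Annotation, Screening-Funnel
    Calibration and Epitope Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational layer of a rabbit B-cell antibody-discovery
    campaign. Annotates cognate VH/VL amino-acid pairs against germline
    references and counts somatic replacement mutations per framework and
    CDR, clusters clones into CDR-H3/CDR-L3 clonotypes, and summarises
    repertoire diversity (CDR-H3 length, replacement load, hydropathy).
    Calibrates plate-assay positivity thresholds by outlier trimming
    followed by a Johnson SU maximum-likelihood fit and its 99 percent
    quantile, runs the multi-assay screening funnel, and groups antibodies
    into epitope bins from cross-competition ELISA matrices via Ward
    hierarchical clustering with gap-based cluster-count selection, PCA
    confirmation and asymmetric-binder detection. Ships seeded synthetic
    generators for repertoires, assay panels and competition matrices so
    every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    mclust,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
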