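Package: mimoScan
Title: Degenerate TCR Recognition-Motif Discovery and Proteome Scanning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-reactive T-cell epitope discovery driven by a
    degenerate T-cell receptor (TCR) recognition motif. Builds per-position
    constraint models from alanine-scanning mutagenesis and stimulatory
    ligand sets, summarises them as position-frequency models with
    sequence-logo information content, compiles degenerate octamer search
    patterns, and scans protein FASTA files for motif-matching peptides with
    HLA-anchor completion and curation filters. Also provides the
    accompanying nonparametric immunoassay statistics (stimulation indices,
    Mann-Whitney, Kruskal-Wallis with Bonferroni correction), a
    gluten-free-diet cohort analysis (PASI response classification, gliadin
    serology thresholding, Fisher exact association), and seeded synthetic
    generators for proteomes, assay tables and cohorts so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
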