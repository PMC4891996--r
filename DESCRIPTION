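Package: tcrbrep
Title: TCR Beta Repertoire Simulation, Annotation and Clonality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for T-cell receptor beta-chain (TCRB) repertoire analysis of
    paired peripheral-blood and cerebrospinal-fluid samples: a seeded synthetic
    repertoire and read simulator with planted clonal expansions and public
    clonotypes, germline V/J assignment and CDR3 junction extraction from raw
    reads, collapsing of unique productive rearrangements into counted
    clonotypes, cell-count-normalized diversity metrics (richness, Shannon
    entropy, evenness), clonal expansion profiling and binning, cross-subject
    and cross-compartment clonotype sharing, exact small-sample Wilcoxon tests
    with a leave-one-out robustness procedure, and CDR3 amino-acid motif
    clustering with position frequency matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'germline-io.R'
    'simulate.R'
    'annotate.R'
    'diversity.R'
    'sharing.R'
    'stats.R'
    'motifs.R'
    'pipeline.R'
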