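Package: qsarscreen
Title: QSAR Classification and Applicability-Domain Virtual Screening for
    Imbalanced Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based virtual screening on heavily imbalanced
    binary activity data, built around the PD-1/PD-L1 immune-checkpoint
    inhibition problem. Covers dataset curation (structure standardization,
    stereochemistry-aware InChI deduplication, label-conflict resolution,
    stratified splits), molecular descriptor generation (MACCS, circular and
    hashed path fingerprints, a frozen 242-column 1D/2D panel, 3D families on
    conformers, and property-weighted voxel-grid descriptors),
    fingerprint-similarity clustering with centroid-based applicability-domain
    filtering, class-balanced random forest, SVM and multilayer-perceptron
    classifiers with out-of-bag validation and importance-based descriptor
    selection, and a multi-criteria screening step that ranks a drug library by
    predicted activity, applicability-domain membership and optional docking
    affinities. Chemistry primitives are delegated to Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
SystemRequirements: Open Babel (>= 3.0, the 'obabel' executable on PATH)
Config/testthat/edition: 3
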