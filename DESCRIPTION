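Package: wfcm
Title: Weighted Families of Contact Maps for Flexible Protein Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes conformational ensembles of flexible and
    intrinsically disordered proteins as a weighted family of contact maps.
    Each conformation is featured by a continuous, orientation- and
    sequence-dependent residue-residue contact function; the resulting
    feature matrix is embedded with UMAP and partitioned with a native
    HDBSCAN implementation; each cluster is summarized by its mean
    omega-contact map, an occupancy weight, secondary-structure
    propensities and radius-of-gyration statistics. Includes a
    parameter-estimation pipeline for the contact function from reference
    structures and seeded synthetic-ensemble generators for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    uwot,
    mclust,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
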