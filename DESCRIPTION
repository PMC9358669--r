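Package: nativems
Title: Native Metabolomics Screening for Protein-Ligand Binding from LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein-ligand binding from post-column protein-infusion
    LC-MS experiments ("native metabolomics"). Deconvolutes multiply charged
    native protein spectra into neutral-mass species, detects chromatographic
    features on deconvoluted mass traces and on small-molecule LC-MS/MS runs,
    pairs protein-complex features with ligand features by mass offset and
    retention time, builds a combined molecular/binding network from MS/MS
    modified-cosine similarity, and quantifies binding via titration-ratio and
    four-parameter logistic dose-response fits. Includes a synthetic-data
    generator that emulates paired native and metabolomics runs with planted
    ground truth, so the whole pipeline is exercisable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
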