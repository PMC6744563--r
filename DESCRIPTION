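Package: msiclust
Title: Unsupervised Spatial Analysis of Imaging Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for unsupervised analysis of MALDI imaging mass
    spectrometry (IMS) data: peak picking on the dataset average spectrum,
    on-tissue screening of ion images, principal-component decomposition of
    the ion-image stack, cosine-similarity hierarchical grouping of molecule
    distributions, and annotation of glycerophospholipid ions via isotope
    envelopes, adduct masses and ppm matching. Includes a synthetic
    brain-phantom generator with a ground-truth manifest so every stage can
    be validated without access to instrument data, plus imzML and
    tab-separated import/export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
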