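Package: scafdiv
Title: Scaffold and Chemical-Space Diversity Analysis of Chemical Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and compares the chemical diversity of compound
    libraries. Computes Bemis-Murcko molecular scaffolds at three
    abstraction levels (graph/node/bond, graph/node, and graph), cyclic
    system retrieval (CSR) curves with their AUC and P50 summary metrics,
    scaled Shannon entropy over the most populated scaffolds, inter- and
    intra-library distances from 166-bit MACCS fingerprints (Soergel
    distance) and six drug-likeness properties (Euclidean distance on
    standardized values), consensus diversity plots with quadrant
    classification, and 2D chemical-space embeddings by PCA and
    generative topographic mapping. Includes a seeded generator of
    chemically valid synthetic libraries with controllable
    scaffold-frequency structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
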