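Package: oscirsa
Title: Representational Similarity Analysis of Oscillatory Power and Phase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links time-frequency representations of multichannel
    electrophysiological recordings to reference representational
    geometries. Builds representational dissimilarity matrices (RDMs)
    from multitaper power and phase patterns at every time-frequency
    coordinate, relates them to two reference RDMs (e.g. V1-like and
    IT-like) by partial-correlation RSA with group statistics and FDR
    control, clusters the RDM stack with correlation-distance k-means
    and an elbow criterion, positions each cluster centroid on a
    low-to-high cortical-level scale, and maps centroids onto layered
    feature hierarchies via a normalized best-matching-layer score.
    Ships a synthetic-data generator with planted, recoverable
    structure (condition-coded oscillatory components in power and in
    phase, coupled reference RDM pairs, morphing layer hierarchies) so
    that every stage has a ground-truth test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
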