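Package: soundscapemap
Title: Eco-Acoustic Index Pipelines for Mapping Urban-Park Soundscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the acoustic environment of a green
    area from a grid of autonomous recorders. Computes per-second
    eco-acoustic indices (ACI, ADI, AEI, H, BI, NDSI and a dynamic spectral
    centroid) from fixed-resolution spectrograms, summarises each index
    time series with seven statistical descriptors, reduces the site-by-
    feature table by principal component analysis, groups sites with
    k-means, DIANA, Ward or PAM clustering under internal validation,
    tests between-cluster differences with rank-based tests, screens a
    recorder fleet with a white-noise ACI tolerance rule, relates clusters
    to NDVI region-of-interest statistics and aural survey labels, and
    renders per-site class maps. A seeded synthetic soundscape generator
    (road-traffic noise gradient, Poisson bird chirps, take-off transients,
    construction beeps) provides ground-truthed studies for testing every
    stage without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
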