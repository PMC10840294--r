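Package: ricessv
Title: Rice Field Mapping from Multi-Temporal Optical and SAR Imagery with
    Spectral Similarity Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies paddy-rice fields in hilly terrain from multi-temporal
    optical reflectance, dual-polarization SAR backscatter and terrain rasters.
    Builds one mean-composited multi-band feature image per phenological stage
    (sowing, transplanting, growing, maturity), derives a rice standard feature
    curve from training samples, scores every pixel with the spectral
    similarity vector (cosine similarity minus min-max-normalized Euclidean
    distance to the curve), calibrates per-stage thresholds by a quartile rule,
    applies a four-stage decision rule, and evaluates the map with
    confusion-matrix metrics plus patch-size and slope recognition analyses.
    Includes a synthetic-scene generator so the whole pipeline is testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
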