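Package: aggrefinger
Title: Single-Particle Fingerprinting of Protein Aggregates from
    Single-Molecule Pulldown and dSTORM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative profiling of nanoscopic protein aggregates
    captured by single-molecule pulldown (SiMPull). Detects and counts
    diffraction-limited puncta in TIRF image stacks, matches two-channel
    detections with a chance-colocalization estimate, measures per-aggregate
    morphology (area, perimeter, eccentricity, skeleton length, localization
    density) from super-resolution localization tables, classifies aggregate
    subpopulations against length/eccentricity/density thresholds, compares
    donor cohorts with interpolated cumulative distributions and subsampled
    Kolmogorov-Smirnov tests, derives a linear-discriminant disease
    signature from donor profiles, and computes total-proteome-corrected
    aggregate-fraction abundance ratios from reporter-ion quantification
    tables. A synthetic-data generator with exported ground truth emulates
    every input so the full pipeline is testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
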