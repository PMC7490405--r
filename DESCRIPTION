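Package: adhertype
Title: Data-Driven Typology of Inhaler Medication Adherence from
    Electronic Monitoring Device Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to derive a multidimensional typology of preventer
    medication adherence from electronic monitoring device (EMD) actuation
    logs of twice-daily inhaled corticosteroid users. Converts timestamped
    actuation events into per-patient half-day dose grids with
    device-malfunction masking, computes five person-level adherence
    measures spanning implementation (dose taking) and persistence
    (treatment intermissions of five or more consecutive days), extracts
    their latent structure by principal component analysis under several
    scaling regimes, forms k-means clusters with the cluster count chosen
    from the within-group sum-of-squares curve, assesses cluster stability
    by bootstrap Jaccard similarity and dissolution rates, and fits a
    pruned single-measure classification tree as an interpretable
    surrogate for cluster membership. A seeded synthetic-cohort generator
    emulates the statistical structure of EMD trial data so the whole
    pipeline is testable without access to patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
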