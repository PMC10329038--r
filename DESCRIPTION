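Package: hiveburst
Title: Collective Locomotor Bursts, Pioneer Bees and Information Flow in
    Honeybee Hives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for per-second honeybee tracking data:
    kinetic-energy activity series, Kleinberg burst detection on
    inverse-rate converted series, waggle-dance / dance-follower / foraging
    trip detection, effective transfer entropy between activity, dance and
    out-of-hive counts, nonnegative matrix factorization (Kullback-Leibler
    multiplicative updates with cophenetic rank selection) to extract
    "pioneer bees" that activate before each burst, and burst-similarity
    analysis via Jaccard distances and non-metric multidimensional scaling.
    Includes an agent-based synthetic-hive generator with ground-truth
    labels for validating every detector.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
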