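Package: baitline
Title: Monitoring, Track-Compliance and Costing Tools for Aerial-Prefeed
    Ground-Toxic Pest Baiting Operations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and analysing ground-based toxic baiting of
    brushtail possums and rats along aerially prefed flight lines. Computes
    the standard New Zealand monitoring indices (chewcard interference index
    CCI, its arcsine-transformed form tCCI, and the residual trap catch index
    RTCI with half-trap-night corrections), card-weighted block-level
    population-reduction estimates with back-transformed asymmetric errors,
    a from-first-principles ANOVA layer (one-way, Type-II two-way, Fisher's
    LSD and Tukey's HSD with a numerically integrated studentized-range
    distribution), GPS track-compliance and baiting-timing summaries, and
    per-hectare cost and coverage models for aerial, ground, and hybrid
    baiting strategies. A seeded synthetic field-operation generator
    reproduces the statistical structure of a two-trial baiting study so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
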