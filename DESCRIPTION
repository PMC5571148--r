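Package: evdist
Title: Ecosystem Vulnerability Distributions from Biomonitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives ecosystem vulnerability distributions (EVDs) from
    site-level species presence/absence records and co-located environmental
    monitoring data. Per-species occurrence is modelled with quadratic-logit
    species distribution models fitted by all-subsets enumeration and
    AIC-based multi-model averaging; the models are stacked into
    site-specific stressor-response curves of relative species richness,
    inverted at a user-selected richness-loss threshold to obtain critical
    stressor levels, and assembled into per-stressor vulnerability
    distributions. Overlaying an EVD with the regional distribution of
    observed stressor levels classifies sites as not-at-risk, at-risk or
    impacted and ranks stressors. Includes collinearity screening by
    sequential variance-inflation-factor elimination, a virtual-landscape
    simulator with known ground truth for method validation, and a staged
    pipeline with plain-text artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
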