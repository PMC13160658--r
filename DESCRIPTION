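Package: cloudsens
Title: Cloud-Model Climate-Change Sensitivity of Montane Forest Upper Limits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the climate-change sensitivity of the upper limit of
    montane deciduous broad-leaved forests (ULMDBs) with the normal cloud
    model. From tables of forest-boundary location points and five impact
    factors (aspect class, terrain relief, mountaintop effect, January mean
    temperature, annual precipitation), the package fits per-site height
    regressions, converts standardized coefficients into normalized factor
    weights, summarises per-mountain weight distributions as cloud digests
    (expectation Ex, entropy En, hyperentropy He) via the backward cloud
    generator, and derives temperature, precipitation and comprehensive
    sensitivity indices (TSI, PSI, CSI) with factor-dominance labels and
    regional aggregates. Includes DEM-derived terrain-factor computation,
    NDVI trend-slope validation via Spearman correlation, a forward cloud
    generator for cloud diagrams, and a fully seeded synthetic-study
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
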