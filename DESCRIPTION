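Package: thermopt
Title: Thermal Performance Inference for Larval and Juvenile Rearing
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for replicated multi-temperature rearing
    experiments on marine invertebrate early life stages. Builds first
    principal-component composite development scores from correlated
    morphometric characters, fits quadratic thermal-performance curves and
    extracts range-clamped thermal optima, and quantifies their uncertainty
    with a two-stage (jar, then larva) cluster bootstrap. Also provides
    binomial mixed models for settlement and cloning proportions, factorial
    growth and fate analyses for juveniles, and a difference-in-differences
    mixed model for righting-response performance under a simulated marine
    heatwave, together with synthetic-data generators carrying known ground
    truth for every experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
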