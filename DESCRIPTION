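Package: aqemu
Title: Gaussian-Process Emulation of Sectoral Emission Impacts on Air
    Quality and Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emulator-based analysis of how anthropogenic emission sectors
    (residential, industrial, land transport, agricultural, power
    generation) drive fine particulate matter (PM2.5) and ozone (O3)
    exposure and the attributable premature-mortality burden. Provides a
    synthetic chemistry-transport surrogate world, maximin Latin hypercube
    experiment designs, per-grid-cell Gaussian-process emulators with
    Matern 5/2 kernels, observation-based concentration scaling, chronic
    exposure metrics (annual-mean PM2.5, 6-monthly-mean daily-maximum
    8-hour O3), GEMM and log-linear exposure-response health impact
    assessment with attribution and subtraction sector accounting,
    measurement-informed emission-change inference by rejection matching
    over an exhaustive configuration grid, and scenario search against
    air-quality targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
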