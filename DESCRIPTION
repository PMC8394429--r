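Package: nixdry
Title: Isothermal Dehydration Kinetics of Nixtamalized Corn Grains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing thin-layer isothermal dehydration of
    nixtamalized corn grains as a function of steeping time. Implements the
    first-order exponential moisture model M(t) = (M0 - ME) exp(-k t) + ME,
    its link to the Fick's-second-law sphere solution through the effective
    diffusivity Deff = k a^2 / pi^2, nonlinear and log-linear recovery of
    (M0, ME, k) from drying trajectories, moisture and dehydration-rate
    isoline surfaces over the (steeping time, drying time) plane, and a
    seeded synthetic-data generator that emulates the five-steeping-time,
    five-replicate experimental design so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
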