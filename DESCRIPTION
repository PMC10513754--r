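Package: maizecast
Title: Maize Yield Estimation by Crop Growth Simulation and Ensemble
    Kalman Filter Assimilation of Remotely Sensed Leaf Area Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order daily-step crop growth simulator for maize
    (potential production, WOFOST-style parameterisation) coupled to the
    calibration and data-assimilation chain used in regional yield
    estimation from optical satellite imagery: FAO-56 solar radiation from
    sunshine hours, vegetation-index regression retrieval of leaf area
    index (NDVI, EVI, NDGI, kNDVI), Sobol variance-based sensitivity
    screening of variety parameters, Metropolis MCMC calibration against
    field LAI, and sequential ensemble Kalman filter assimilation of
    stage-wise LAI maps into the simulator, in both a calibrated
    parameter-set mode and a single growth-weakness-factor mode for inbred
    seed-production lines. Includes seeded synthetic-scene generators so
    the whole pipeline can be exercised and validated end to end in twin
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
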