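Package: spoilwarn
Title: Gas-Sensor Chemometrics for Apple Spoilage Early Warning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building early-warning models of apple spoilage from
    warehouse gas-sensor arrays. Simulates multi-day warehouse acquisitions
    for six channels (temperature, humidity, CO2, C2H4, O2, VOC), flattens
    500 x 6 recordings into 3000-element feature vectors, and fits sparse
    linear warning models via partial least squares (PLS) regression wrapped
    in four metaheuristic variable-selection algorithms: genetic algorithm
    (GA), simulated annealing (SA), ant colony optimization (ACO), and
    competitive adaptive reweighted sampling (CARS). Ships a published
    20-term reference warning model with spoilage grade bands, model
    serialization, and an end-to-end simulate/train/monitor/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
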