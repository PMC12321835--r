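Package: strawsim
Title: Source-Sink Dry-Matter Simulation of Greenhouse Strawberry Yield
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Daily time-step simulator of greenhouse strawberry
    (Fragaria x ananassa) growth and fresh-weight yield for Japanese
    forcing culture. Dry-matter production is computed from intercepted
    photosynthetically active radiation via a Beer-Lambert canopy and a
    constant light-use efficiency; daily assimilate is partitioned between
    vegetative organs and fruit clusters according to the sink strength of
    every leaf and inflorescence present that day, each following a
    degree-day logistic potential-growth curve. Includes light-use
    efficiency calibration by regression, validation statistics (RMSE,
    RRMSE, R-squared, interval fruit fraction), a synthetic
    forcing-culture scenario generator (climate, flowering schedule, leaf
    area, top-down canopy images), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
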