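Package: iptet
Title: Improved Priestley-Taylor Evapotranspiration Modelling for
    Greenhouse Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates hourly and daily evapotranspiration (ET) of
    greenhouse crops with an improved Priestley-Taylor model that
    partitions net radiation between canopy and soil through Beer-Lambert
    extinction and modulates the Priestley-Taylor coefficient with leaf
    senescence, air temperature and topsoil water constraints.  Includes
    a path-analysis decomposition of the meteorological drivers of ET
    (direct, indirect and decision coefficients), model evaluation
    statistics (RMSE, MAE, Willmott's index of agreement) and seeded
    synthetic greenhouse-season generators so the full pipeline can be
    exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
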