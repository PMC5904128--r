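Package: firecarbon
Title: Process-Based Wildfire, Burned Area and Land Carbon Attribution on Synthetic Forcing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale gridded fire-carbon pipeline. Implements a
    process-based wildfire module built on the fire triangle (fuel,
    moisture, ignition), with human ignitions and fire suppression both
    expressed as functions of population density, a geometric
    fire-duration law, elliptical fire spread, crop masking, and a
    minimal two-pool land carbon bookkeeping that converts burned area
    into CO2 emissions. Seeded synthetic forcing generators (population,
    cropland, lightning, soil wetness, wind, CO2) drive a factorial
    simulation design in which forcings are switched on individually or
    frozen at a reference year, so the contribution of each driver to
    burned-area and fire-emission trends can be attributed by
    differencing. Includes trend, overlap, moving-average, correlation
    and emergent-curve diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
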