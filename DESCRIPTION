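Package: mabox
Title: Gas-Exchange Modelling and Blower Control for Modified-Atmosphere
    Storage Boxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enzyme-kinetic respiration, forced and natural oxygen diffusion,
    and duty-cycle blower control for modified-atmosphere (MA) storage of
    fresh produce. Implements Michaelis-Menten respiration with carbon
    dioxide inhibition and Arrhenius temperature dependence, the hourly
    blower-ON-frequency (BOF) controller that balances respiratory oxygen
    demand against forced and passive air exchange, a time-stepped headspace
    simulator under piecewise-constant temperature profiles, and Monte Carlo
    plus one-at-a-time variability analyses of the controller (sensitivity
    ranges, Pareto contributions, parameter-BOF correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
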