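Package: mozpump
Title: Reduced-Order Model of the Mosquito Two-Pump Drinking System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter fluid-mechanical model of drinking in the
    mosquito head: the cibarial and pharyngeal pumps are prolate spheroids
    driving quasi-steady Hagen-Poiseuille flow through the feeding canal,
    pharynx, and esophagus, with direction-dependent valve impedances.
    Simulates the continuous and burst drinking modes, computes flows,
    pressures, and pump power, performs virtual single-pump knockouts, and
    evaluates the capillary meniscus priming threshold. Also includes a
    kinematics pipeline that extracts pump-cycle timing variables from
    x-ray region-of-interest intensity time series, together with a
    ground-truthed synthetic-trace generator for validating it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
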