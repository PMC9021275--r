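Package: lophoswim
Title: Swimming Dynamics of a Lophotrichous Bacterium by Regularized
    Stokeslets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a model lophotrichous bacterium: a rigid capsule cell
    body coupled by a penalty method to Stokes flow, driven by a single polar
    flagellum modelled as a Kirchhoff rod (compliant hook plus left-handed
    helical filament) rotated by a motor torque schedule.  The fluid coupling
    uses regularized Stokeslets and rotlets with an exact image system for a
    no-slip plane wall.  Includes classification of push, pull, wrapping and
    overwhirling swimming modes, pause-mediated reorientation statistics
    (turn angle and longitude), and near-wall escape/trapping analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
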