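Package: lifespace
Title: GPS Life-Space Mobility Indicators and Day-Level Poisson Mixed Models
Version: 0.1.0
Authors@R:
    person("MOBILE", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw GPS fixes from older adults into daily
    out-of-home mobility indicators (time out of home in minutes and the
    daily convex-hull area in square kilometres), to compute home-centred
    built-environment exposures (intersection density, green-space share,
    walkable reach of transit and health facilities) from vector map layers,
    and to model day-level mobility counts with a Poisson generalized linear
    mixed model with person random intercepts fitted by Laplace-approximated
    maximum likelihood. Includes seeded synthetic-data generators for
    cohorts, environments, trajectories and outcomes with known ground
    truth, and a command-line pipeline from simulation to coefficient
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
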