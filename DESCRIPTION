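Package: cellign
Title: Alignment Dynamics of Two Interacting Ellipse-Shaped Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the symmetric two-cell model of
    self-propelled ellipse-shaped cells interacting through overlap avoidance.
    Provides the exact overlap geometry of the mirror-symmetric configuration
    (analytic boundary intersection points, region classification), the
    piecewise-smooth governing equations with event-aware trajectory
    integration, closed-form results for the zero-propulsion rigid system
    (trajectory curves, final angles, finite interaction times), matched
    asymptotic approximations near the perfect-alignment steady state, the
    small-propulsion slow-manifold reduction, separatrix computation, and the
    alignment-strength statistic S_align.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
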