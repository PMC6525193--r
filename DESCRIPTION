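Package: soursim
Title: Sulfur- and Nitrogen-Cycle Reaction Networks for Nitrate Treatment of Reservoir Souring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds bioenergetic microbial community reactions from electron-equivalent
    half-reactions (sulfate reduction, heterotrophic and autotrophic nitrate/nitrite
    reduction via the DNRA and denitrification pathways, sulfide and sulfur oxidation),
    enumerates admissible community scenarios, simulates well-mixed batch kinetics under
    a Monod rate law with nitrite product inhibition, estimates kinetic parameters with a
    two-stage genetic-algorithm plus local-refinement fit, screens scenarios by sum of
    squared errors, and simulates packed-bed column experiments with a one-dimensional
    finite-volume reactive transport model using operator splitting. Includes mechanism
    dissection tools (inhibition/biocompetition/sulfur-cycling toggles, minimum and
    required inhibitory nitrate concentrations, nitrite-to-nitrate reduction rate ratio
    sweeps) and a synthetic data generator for batch and flow designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
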