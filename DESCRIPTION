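Package: loopkit
Title: Cyclization and Decyclization Kinetics of Short DNA with Sticky Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the looping (cyclization) and unlooping (decyclization)
    kinetics of ~100-bp DNA with complementary single-stranded overhangs.
    Implements a finite-width, intrinsically curved rigid base-pair elastic
    model with constrained minimization of teardrop and nicked loop
    conformations, transition-state looping-rate profiles over rotational
    register angles, wormlike-chain J factors with and without helical
    alignment, a three-state (unlooped / teardrop / smooth) kinetic model
    with exact stochastic simulation, and a synthetic single-molecule FRET
    pipeline (trace generation, smoothing, transition detection, censored
    first-passage rate estimation) that turns trajectories into rates and
    experimental J factors. Tibble-first interfaces with ggplot2 plotting
    and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
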