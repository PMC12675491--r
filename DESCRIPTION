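Package: sinkvel
Title: Sedimentation Velocity of Drifting Macrophytes and Plastic Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the still-water sedimentation (settling) velocity of
    drifting marine macrophytes and negatively buoyant plastic objects from
    three measurable traits: volume, wet weight and shape. Implements the
    nominal diameter and Corey shape factor descriptors with the
    flattened-thallus and branched-thallus derivation routes, standard
    seawater density and kinematic viscosity correlations, three empirical
    drag-based velocity models of increasing shape dependence, a real-coded
    genetic algorithm for refitting model constants to settling observations,
    evaluation metrics (median squared deviation and observed-versus-predicted
    r squared), and a synthetic-data generator that emulates the trait and
    replicate-velocity structure of settling-column experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
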