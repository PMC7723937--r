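Package: cartatlas
Title: Atlas-Based Finite-Element Modelling of Knee Cartilage Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rapid generation and desk-scale simulation of medial-compartment
    knee cartilage finite-element models from five anatomical dimension
    measurements. Provides template-atlas matching by normalized-dimension
    RMSE with anisotropic mesh scaling, simplified body-weight-scaled gait
    loading with meniscus-support subtraction, a fibril-reinforced
    poroviscoelastic (FRPVE) cartilage material with depth-dependent
    Benninghoff arcade fibril orientations, a mixed displacement-pore-pressure
    poroelastic hexahedral solver with rigid-condyle penalty contact,
    stance-phase response summarization (peak and contact-averaged principal
    stresses and strains, fibril strain, pore pressure), intrarater
    reliability statistics (ICC(2,1) absolute agreement with F-based
    confidence intervals), and nonparametric one-dimensional statistical
    parametric mapping by sign-flip permutation for paired trajectory
    comparison. Includes seeded synthetic generators for atlas libraries,
    subject dimensions, rater tables and paired trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
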