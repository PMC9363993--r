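Package: cultdiff
Title: Linked Acquisition and Production Models of Cultural Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative agent-based model of cultural diffusion on social
    networks in which knowledge acquisition through social transmission
    (a network-based diffusion process) and behavioural production through
    reinforcement learning (an experience-weighted attraction process) are
    linked sub-models. Provides diffusion statistics (time-to-diffusion,
    order divergence, production delay), continuous time-of-acquisition
    diffusion analysis (TADAc) with AICc model comparison, Bayesian
    estimation of production-rule parameters from behavioural time series,
    and orchestration of sensitivity sweeps and inference batteries on
    simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
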