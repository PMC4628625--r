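Package: fractalmsd
Title: Fractal Crossover Model for Anomalous Diffusion from Mean-Square
    Displacement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form model of a particle trajectory crossing over from
    short-time ballistic motion to long-time anomalous (sub- or super-)
    diffusion, built on a scale-dependent trajectory fractal dimension.
    Provides the forward mean-square-displacement (MSD) law at all times,
    its ballistic and power-law asymptotes, and estimators for the mean
    free path, the Brownian step time, the anomalous diffusion exponent
    and the transport coefficient from single-particle-tracking MSD data.
    Includes a synthetic-data module for model-consistent noisy MSD series
    and stand-in trajectories, CSV/JSON input and output, and a command
    line interface for fitting, prediction and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
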