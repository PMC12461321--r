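Package: desgp
Title: Gaussian-Process Property Prediction and Screening for Deep Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts density, viscosity and melting temperature of deep
    eutectic solvents (DESs) from COSMO-RS sigma profiles using Gaussian-process
    regression. Builds mole-fraction-weighted mixture descriptors from 61-bin
    sigma profiles, fits GPs with RBF, rational-quadratic or Matern 3/2 kernels
    plus a White noise term by log-marginal-likelihood maximisation, benchmarks
    kernel and normalisation choices on stratified three-way hold-out splits,
    enumerates and screens the binary 1:1 design space with melting-temperature
    liquidity gates, and maps the DES chemical space to two dimensions with
    probabilistic PCA. A synthetic-data module generates sigma-profile-shaped
    fixtures with known latent structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
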