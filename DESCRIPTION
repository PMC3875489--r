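Package: turgor
Title: Turgor-Driven Stomatal Conductance with Cavitation Tradeoff and
    Hierarchical Bayesian Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-mechanistic model of leaf stomatal conductance for shrubs and
    subshrubs: conductance proportional to guard-cell turgor, osmotic pressure
    adjusted by net photosynthesis, and soil-to-leaf hydraulic conductance that
    declines hyperbolically with xylem tension under an efficiency-safety
    tradeoff. Includes tools to ingest and harmonize diurnal leaf gas-exchange
    tables, a synthetic-data generator with known truth, a Metropolis-within-Gibbs
    sampler for three-level hierarchical Bayesian fitting with latent daily soil
    water potentials, deviance/DIC model comparison, and forward behavioral
    analysis (response surfaces, closure potentials, vulnerability curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
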