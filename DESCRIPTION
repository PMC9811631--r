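Package: rhizosge
Title: Social Genetic Effects and Host Discrimination in Rhizobium
    Co-Inoculation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of host discrimination
    in two-strain rhizobium co-inoculation experiments. Generates the full
    randomized complete block co-inoculation design, simulates phenotypes
    with direct genetic effects (DGE), main social genetic effects (SGE)
    and genotype-by-genotype (G x G) social effects, fits constrained REML
    mixed models that partition phenotypic variance into those components,
    tests components by likelihood-ratio tests, computes the partner-choice
    and sanctions regressions on strain genotypic means, and evaluates host
    benefit as the deviation of two-strain host fitness from the neutral
    expectation under no partner choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    generics,
    ggplot2,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
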