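Package: coprokin
Title: Coproporphyrin-I PBPK Modeling of OATP1B-Mediated Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lumped physiologically based pharmacokinetic (PBPK) model of
    coproporphyrin-I (CP-I), the endogenous biomarker of hepatic OATP1B1/1B3
    transport. Simulates CP-I plasma baseline across ethnicity, SLCO1B1
    c.521T>C genotype, and sex; predicts transporter-mediated drug-biomarker
    and drug-victim interactions under competitive inhibition; estimates in
    vivo OATP1B inhibition constants from interaction data and quantifies
    their sensitivity to the assumed renal elimination fraction; and
    simulates phase-I trial designs to compare Cmax-ratio and AUC-ratio
    monitoring metrics. Includes fold-error, Guest-criterion and geometric
    mean fold error model evaluation statistics, and synthetic clinical-style
    data generators for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
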