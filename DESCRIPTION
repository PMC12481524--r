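Package: tmpsulfa
Title: Population Pharmacokinetics of Trimethoprim-Sulfonamide Combinations in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of trimethoprim (TMP)
    combined with sulfadiazine (SDZ), sulfamethoxazole (SMX) or sulfadimethoxine
    (SDMX) in growing pigs. Provides closed-form one- and two-compartment
    concentration models with first-order absorption and dose superposition,
    a nonlinear mixed-effects population model with inter-individual and
    inter-occasion variability and a bodyweight power covariate, SAEM-based
    estimation with interval- and left-censored observations below the limit
    of quantification, model-evaluation diagnostics (IWRES, PWRES, NPDE,
    prediction-corrected VPC), protein-binding correction to free plasma
    concentrations, and Monte-Carlo herd simulations of free sulfonamide to
    trimethoprim concentration ratios against the 1:19 synergy target and
    the 1:10-1:50 band.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
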