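Package: pelletpk
Title: Characterization, Release Kinetics and Pharmacokinetics of
    Extended-Release Pellet Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis chain for quality-by-design development of coated
    extended-release pellets: micromeritic flow properties and pellet shape
    morphometrics, model-dependent dissolution kinetics (zero-order,
    first-order, Higuchi, Hixson-Crowell, Baker-Lonsdale, Jander,
    Korsmeyer-Peppas) with model ranking, mean dissolution time, dissolution
    efficiency and the f2 similarity factor, central composite rotatable
    designs with response-surface fit summaries (PRESS, predicted R-squared,
    sequential ANOVA), non-compartmental pharmacokinetic analysis, average
    bioequivalence on 2x2 crossover studies (GMR, 90% CI, TOST),
    bioanalytical validation metrics, regression-based shelf-life
    estimation, and seeded synthetic-data generators for every input table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
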