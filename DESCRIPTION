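Package: leukosim
Title: Virtual-Patient Simulation of Leukopoiesis and Acute Myeloid Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-lineage, multi-compartment ordinary differential equation
    model of white blood cell formation (neutrophils, lymphocytes, monocytes)
    with cytokine-mediated feedback, induction chemotherapy, and a
    feedback-free leukemic clone. Provides a virtual-cohort workflow:
    log-space Latin hypercube sampling of uncertain rate parameters,
    equilibrium screening against seven dynamic acceptability criteria,
    separatrix constraints that learn pairwise parameter relationships,
    partial rank correlation sensitivity analysis, k-means stratification of
    simulated recovery dynamics into representative patients, and untreated
    AML progression with survival endpoints and cancer-parameter screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
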