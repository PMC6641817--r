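Package: pretermcascade
Title: Decision-Tree Cohort Modelling of Preterm Neonatal Mortality and
    Intervention Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic decision-tree cohort model of neonatal mortality
    among preterm births across home, clinic, and hospital levels of care.
    Expected deaths from respiratory distress syndrome, intraventricular
    hemorrhage, necrotizing enterocolitis, sepsis, birth asphyxia, and low
    birth weight are computed from subcondition prevalences and untreated
    case-fatality rates, attenuated by a coverage cascade (penetration x
    utilization x efficacy, with diagnosis-gated treatment and optional
    referral transfer). Includes scenario transforms for incremental
    (+20 percentage point) and universal (98%) coverage scale-up, a bundled
    sub-Saharan Africa 2015 parameterization, rounded scenario reporting,
    a random-parameter generator, and an individual-level Monte Carlo
    microsimulation oracle for validating the deterministic arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
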