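Package: ketopbpk
Title: Whole-Body Parent-Metabolite PBPK Model of Ketoconazole and Its
    Metabolites as Interaction Perpetrators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) model
    of oral ketoconazole and its sequential metabolites N-deacetylketoconazole
    (M1) and N-deacetyl-N-hydroxyketoconazole (M2).  Simulates gastrointestinal
    transit, particle dissolution and prandial-state (drug-food interaction)
    effects, Michaelis-Menten metabolism with competitive reversible inhibition
    of CYP3A4 and P-glycoprotein, biliary and renal excretion, and
    drug-drug-interaction scenarios in which the parent alone or together with
    its metabolites acts as the perpetrator against victim drugs.  Includes
    non-compartmental analysis, model evaluation statistics (mean relative
    deviation, geometric mean fold error, Guest acceptance limits), parameter
    fitting, local sensitivity analysis, and a synthetic-data generator that
    emulates mean plasma concentration-time profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
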