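Package: VariantPenetrance
Title: Penetrance and Expressivity Analysis for Monogenic Metabolic Conditions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of penetrance and expressivity of rare clinically
    significant variants for monogenic dyslipidemias, monogenic obesity and
    maturity-onset diabetes of the young (MODY) from biobank-scale exome and
    phenotype data. Provides a deterministic rule engine for ClinVar-based
    variant triage and curation of predicted loss-of-function variants
    (nonsense-mediated-decay escape, splice-site rescue, expression-aware
    downgrades), phenotype harmonization (lipid-lowering medication
    adjustment, unit conversion, glycemia classification), carrier versus
    non-carrier burden regression including Firth penalized logistic
    regression for rare binary outcomes, exact Clopper-Pearson penetrance
    intervals, polygenic-score tail contrasts and carrier-only models,
    truncated-normal modelling of phenotypic ascertainment bias, and a
    synthetic cohort generator that emulates the statistical structure of
    restricted biobank data so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
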