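Package: fhburden
Title: Familial Hypercholesterolemia Burden Screening for Population Biobanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the genetic burden of familial
    hypercholesterolemia (FH) in population biobanks: medication-corrected
    LDL cholesterol, modified Dutch Lipid Clinic Network (DLCN) scoring and
    classification, pathogenic-variant carrier detection with estimated
    clinical penetrance, dual-caller structural-variant consensus by
    reciprocal overlap, an 11-SNP LDL-C polygenic score with
    polygenic-inheritance assessment, and the supporting genetic-epidemiology
    statistics (prevalence, Woolf odds-ratio intervals, chi-square
    cross-tabs, one-way ANOVA). A synthetic biobank generator reproduces the
    statistical structure of an access-controlled cohort so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
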