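Package: mosaicArrest
Title: Mosaic Aneuploidy, Abnormal Cleavage, and Arrest in Preimplantation Embryo Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates IVF embryo cohorts carrying meiotic and mitotic (mosaic)
    aneuploidies, generates low-coverage binned read counts for trophectoderm
    biopsies and whole arrested embryos, calls chromosome- and arm-level copy
    number from fractional read-depth displacement, classifies aneuploidy
    origin by the 30-70% displacement rule, assigns embryos to five mutually
    exclusive copy-number categories, and models the probability of
    developmental arrest with contingency statistics, quasi-likelihood trend
    models, and binomial generalized linear mixed models with average marginal
    effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
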