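Package: geroscreen
Title: Transcriptomic Age Classifiers and In Silico Geroprotector Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds young-versus-old transcriptomic age classifiers from
    age-stratified expression cohorts, scores drug perturbations by their
    ability to shift a prototypical "middle age" transcriptome toward a
    young classification, ranks compounds by cross-model hypergeometric
    enrichment with false discovery control, and analyses downstream
    organismal validation data (Kaplan-Meier survival, log-rank tests,
    and population activity curves from worm position logs). Includes a
    synthetic-data module that emulates the cohort, perturbation and
    lifespan-machine inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    randomForest,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
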