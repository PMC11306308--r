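Package: marginlibs
Title: Bony Resection Margin Assessment from LIBS Electrolyte Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for laser-induced breakdown
    spectroscopy (LIBS) assessment of bony resection margins in bone-invasive
    oral cancer. Generates seeded synthetic LIBS cohorts with four
    margin-distance classes (tumor, very close, close, clear), converts raw
    emission spectra into potassium, soluble-calcium and Ca/K electrolyte
    values via baseline deduction, baseline-peak normalization and windowed
    peak-area integration, and reproduces the study's statistical surfaces:
    per-class medians with Kruskal-Wallis and Dunn post hoc tests,
    covariate-adjusted logistic regression for electrolyte tracking across
    margin transitions, and ROC/Youden threshold rules cascaded into a
    four-class margin-status classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
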