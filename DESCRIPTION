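Package: adenoquant
Title: Quantification Pipelines for Murine Adenomyosis Fertility Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification
    workflows used in tamoxifen-induced murine adenomyosis studies:
    compartment-wise immunofluorescence quantification of progesterone
    receptor (PGR) staining with automatic Otsu binarization,
    depth-of-invasion (Bird) grading of adenomyotic foci, rule-based
    estrous-stage calling from vaginal smear cell counts with cyclicity
    metrics, ovarian follicle densitometry, relative qPCR expression by
    the 2^-ddCt method with dual reference genes, Western densitometry
    fold changes, and breeding-trial fertility statistics (exact
    Mann-Whitney, two-way ANOVA).  A synthetic-data generator produces
    every input with known ground truth so each stage is verifiable
    without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
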