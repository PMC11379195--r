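Package: methpanel
Title: CpG Panel Selection and Neural-Network Classification of DNA Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequential diagnostic classification of tumor versus normal tissue
    from Illumina 450k beta-value matrices. Implements missing-value pruning
    (15 percent site-then-patient filters), per-site mean imputation,
    binarization at the 0.3 methylation cutoff, reproducible 70/20/10 data
    splits, iterative masked depth-2 entropy decision trees for CpG biomarker
    panel selection, a median-based separation-score filter, a from-scratch
    feed-forward sigmoid network trained by backpropagation, and ROC/AUC and
    PCA quality-control evaluation. Includes a synthetic tumor/normal cohort
    generator with planted discriminative CpG sites and structured
    missingness, plus readers and writers for GDC-style per-sample
    methylation files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
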