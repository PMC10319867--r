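Package: pepscreen
Title: Plasma Epitome Profiling: Normalization, Qualification and Biomarker Screening for Antibody Biochips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-binder capture inhibition assay (sbCIA)
    antibody-biochip data used in plasma epitome profiling. Covers normalization of
    raw relative light units (RLU) to RLU/RLUmax percent signals with replicate
    averaging and capping, coefficient-of-variation quality control, four-parameter
    logistic qualification of inhibition curves, a mimotope-redundancy statistic for
    phage-display peptide sets, pooled-sample differential screening with Venn
    partitioning and correlation-structure summaries, nonparametric biomarker panel
    selection with logistic-regression reporting and cross-validated ROC evaluation,
    and two-state surface plasmon resonance binding kinetics. A synthetic-data module
    generates cohorts, biochip runs, peptide sets, inhibition curves and sensorgrams
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pROC,
    e1071,
    class,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
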