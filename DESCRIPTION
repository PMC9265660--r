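Package: ebmgml
Title: Three-Stage Super-Efficiency EBM Data Envelopment Analysis with
    Global Malmquist-Luenberger Productivity Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures resource-utilization efficiency of production units
    under an undesirable-output (carbon) constraint using a three-stage
    procedure: (1) input-oriented super-efficiency epsilon-based-measure
    (EBM) data envelopment analysis on a global frontier, (2) stochastic
    frontier regression of the stage-one input slacks on environmental
    covariates with JLMS separation of management inefficiency from
    statistical noise, followed by max-based harmonization of the inputs,
    and (3) re-scoring on the adjusted inputs.  Total-factor-productivity
    change is measured by the global Malmquist-Luenberger index and
    decomposed into efficiency-change and technology-change factors.
    Includes a synthetic panel generator with full ground truth for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
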