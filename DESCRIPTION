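Package: nrscreen
Title: Nuclear Receptor Immune-Evasion Screening in Tumor Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes nuclear receptors (and their downstream effectors)
    as candidate tumor-intrinsic regulators of antitumor immunity from bulk
    and single-cell melanoma transcriptomes. Implements a rank-percentile
    IFN-gamma signature index, a Spearman correlation screen against the
    ten-gene IFN-gamma signature, Kaplan-Meier / log-rank survival
    stratification by expression quartiles or z-score cutoffs, a
    single-cell percent-expression (tumor-intrinsic) filter with a
    responder versus nonresponder contrast, and a three-compartment
    differential-expression intersection triage of candidate effectors.
    A synthetic cohort generator with planted ground truth makes the whole
    cascade testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, Survival, GeneExpression,
    ImmunoOncology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'correlation-screen.R'
    'effector-triage.R'
    'ifng-index.R'
    'io.R'
    'methods.R'
    'nrscreen-package.R'
    'panels.R'
    'pipeline.R'
    'rank-stats.R'
    'sc-screen.R'
    'simulate-bulk.R'
    'simulate-de.R'
    'simulate-sc.R'
    'surv-stats.R'
    'survival-screen.R'
    'utils.R'
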