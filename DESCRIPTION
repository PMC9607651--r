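Package: aacscore
Title: Quantitative and Semiquantitative Scoring of Abdominal Aortic
    Calcification with Reliability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the quantitative computer-assisted (QC) abdominal
    aortic calcification score from calibrated lateral lumbar-spine
    radiograph annotations, together with the back-calculated
    semiquantitative (SC) and operator-entered visual (SV, Kauppila 0-24)
    scores.  Annotations carry five intervertebral boundary lines
    (T12-L1 through L4-L5), anterior and posterior aortic wall axes, and
    operator-drawn calcified tracts as polylines; geometry is reduced to
    arc-length intervals on the wall axes, clipped to the scoring region
    and merged before scoring.  A full repeatability and reproducibility
    battery is included: Bland-Altman limits of agreement, repetition
    regression, ICC(2,1) with F-based confidence intervals, standard
    error of measurement (SEM), minimum detectable difference (MDD),
    exact paired Wilcoxon signed-rank test-retest, and between-score
    agreement analysis.  A synthetic-data generator produces annotations
    with known calcified fraction and measurement tables with known
    variance components, so every operation is testable without
    radiographs.  A command-line interface covers scoring, reliability
    reporting, agreement analysis and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aacscore-package.R'
    'annotation.R'
    'cli.R'
    'geometry.R'
    'reliability.R'
    'scoring.R'
    'synthetic.R'
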