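# aacscore

Scoring of abdominal aortic calcification (AAC) from annotated lateral
lumbar-spine radiographs, with a full measurement-reliability toolbox.

## The problem

Vascular calcification of the abdominal aorta is routinely graded on lateral
lumbar-spine radiographs.  The standard instrument is the semiquantitative
visual score (the Kauppila 0–24 score, here **SV**): the aorta in front of
vertebrae L1–L4 is split into four tracts by the intervertebral spaces, the
anterior and posterior wall of each tract is graded 0–3 by the visually
estimated calcified fraction (absent = 0, < 1/3 = 1, 1/3–2/3 = 2, > 2/3 = 3),
and the eight tertiles are summed.  Discreteness and visual estimation both
limit its precision, which matters when short follow-up intervals must
distinguish progression from measurement noise.

`aacscore` implements a quantitative computer-assisted alternative and its
semiquantitative companion, computed from geometric annotations (no image
processing involved — the package consumes the operator's drawn geometry):

- **QC** — the relative calcified length of the abdominal aorta: the operator
  traces calcified tracts along the anterior and posterior aortic walls; the
  package projects them onto the wall axes, clips them to the region between
  the T12-L1 and L4-L5 intervertebral boundary lines, merges overlaps, and
  divides the total calcified length by the total wall length,

  QC_native = Σ_walls |calcified ∩ region| / Σ_walls |region| ∈ [0, 1],

  reported as QC = 24 × QC_native for direct comparison with SV.
- **SC** — the Kauppila tertile rules applied to the *traced* per-segment
  fractions (back-calculated from the same geometry), isolating the effect of
  discretisation from that of visual estimation.
- **SV** — the operator's visual score, carried through unaltered.

The reliability module provides the statistics battery used to compare such
scores: Bland–Altman limits of agreement, repetition regression (R²),
ICC(2,1) (two-way random effects, absolute agreement, single measures) with
F-based 95% CI, the standard error of measurement (SEM, the within-cell root
mean square of a subject × operator ANOVA with repetitions as replicates),
the minimum detectable difference MDD = 1.96·√2·SEM, an exact paired Wilcoxon
signed-rank test for test–retest data, and between-score Bland–Altman
agreement with a difference-vs-mean trend slope.

A synthetic-data generator builds annotations with a known calcified
fraction, an operator-noise model (arc-length endpoint jitter, missed
tracts, visual entry error) and two-way variance-components measurement
tables, so the whole pipeline is testable without radiographs.

## Worked example

```r
library(aacscore)

path <- system.file("extdata", "synthetic_annotation_example.json",
                    package = "aacscore")
ann <- readAnnotation(path)
scoreTriple(ann)
#> ScoreTriple  subject EX01  operator demo  repetition 1
#>   QC (native): 0.2800   QC (0-24): 6.7200
#>   SC: 10   SV: 10
#>          anterior_L1 anterior_L2 anterior_L3 anterior_L4 posterior_L1
#> fraction      0.2243       0.507      0.2846      0.1046       0.5437
#> tertile       1.0000       2.000      1.0000      1.0000       2.0000
#>          posterior_L2 posterior_L3 posterior_L4
#> fraction       0.1768        0.153       0.2481
#> tertile        1.0000        1.000       1.0000
```

28% of the two walls is calcified, so QC = 24 × 0.28 = 6.72.  Each
wall-segment fraction maps to its tertile (e.g. anterior L2 at 0.507 → 2);
the tertiles sum to SC = 10.  The discrete score sits well above the
continuum score — several segments carry short tracts that earn a full
tertile point each — which is exactly the divergence mechanism the discrete
scale exhibits.

A reliability study on simulated operators:

```r
cohort <- generateCohort(nSubjects = 8, nOperators = 5, seed = 5,
                         noise = operatorNoiseConfig(endpointJitterSd = 1.5,
                                                     svEntrySd = 1))
tab <- scoresToMeasurementTable(cohort$scores)
reliabilityReport(tab)        # B-A, R², ICC(2,1)+CI, SEM, MDD per score type
scoreAgreement(tab, "SV", "QC", repetition = 2)
```

The same operations are scriptable through the CLI installed at
`exec/aacscore`:

```sh
aacscore simulate cohort --config cohort.json --out-dir out/ --seed 5
aacscore reliability out/scores.csv --out out/report.csv
aacscore agreement out/scores.csv --pair SV,QC --repetition 2 --out out/agreement.csv
aacscore score annotation.json --out scores.csv
```

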