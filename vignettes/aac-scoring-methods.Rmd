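---
title: "Quantitative AAC scoring and its reliability statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative AAC scoring and its reliability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacscore)
```

## The measurement model

An annotation of one lateral lumbar-spine radiograph carries, in image-space
millimetres (pixel indices × pixel spacing; origin top-left, y growing
caudally):

* five intervertebral **boundary lines** (T12-L1, L1-L2, L2-L3, L3-L4,
  L4-L5), each stored as two points of an infinite line;
* two **wall axes**, the anterior and posterior aortic walls drawn as
  cranio-caudally oriented polylines;
* zero or more **calcified tracts**, one polyline per contiguous calcified
  stretch, each assigned to one wall;
* optionally the operator's visual Kauppila score (SV, an integer 0–24).

All scoring reduces this geometry to one-dimensional arc-length intervals:

1. each boundary line is intersected with each wall axis; where a wavy
   hand-drawn axis crosses a line more than once, the most cranial (smallest
   arc-length) intersection is used, a deterministic tie-break;
2. each tract vertex is projected to its nearest point on its wall axis, and
   the tract becomes the `[min, max]` hull of the projected arc positions —
   gaps inside one drawing are deliberately not inferred, because one drawing
   represents one contiguous calcified stretch (distinct stretches are
   distinct tracts);
3. intervals are clipped to the scoring region `[b0, b4)` between the
   T12-L1 and L4-L5 positions (tracts drawn beyond the outer boundaries are
   ignored) and merged into a disjoint union, so overlapping or duplicated
   drawings are never double-counted.

Intervals are half-open, `[start, end)`: two tracts that abut merge exactly
and no point is counted twice.  Whether tract length should be measured along
the drawn polyline or along its projection on the wall axis is a genuinely
open design point; this package projects, which makes the score independent
of hand-tremor perpendicular to the wall and bounds every per-wall calcified
length by the wall's region length.

### The three scores

With `L_w` the region length of wall `w` and `C_w` its merged-clipped
calcified length:

* **QC (native)** = `(C_ant + C_post) / (L_ant + L_post)` ∈ [0, 1].  The
  denominator pools the two per-wall lengths rather than doubling a single
  aorta length because the two hand-drawn axes generally differ in length.
  Reported QC is 24 × native, never rounded.
* **SC**: the region of each wall is partitioned at the boundary positions
  into four segments (L1..L4); each of the eight wall-segments receives the
  Kauppila tertile of its calcified fraction, and SC is their sum.
* **SV** is operator input, validated to [0, 24] and passed through —
  software never alters a visual judgement.

The tertile map reads the verbal rule "absent = 0, less than 1/3 = 1, from
1/3 to 2/3 = 2, more than 2/3 = 3" with closed edges at both 1/3 and 2/3
(an exact fraction of 1/3 or 2/3 maps to 2).  The rule text does not settle
the edges; closing the middle band is the reading that keeps both quoted
inequalities strict.  Fractions below 1e-9 are treated as absent to absorb
floating-point dust from the interval arithmetic.

### Why QC and SC diverge

A short tract straddling one intervertebral boundary contributes a tertile
point in *each* adjacent segment — 2 of 24 discrete points — while adding
almost nothing to the continuum score.  Repeated over several boundaries and
both walls, the discrete score inflates with an increasing trend against the
pair mean.  This mechanism is constructible on demand with the generator's
`boundary_straddling` placement and is asserted in the test suite.

## Reliability statistics

* **Bland–Altman**: differences `x2 − x1`, SD with the n−1 denominator,
  limits of agreement mean ± 1.96 SD.  The width 3.92·SD is reported as
  `ci_width`, the single-figure repeatability number used to compare scores
  on the 0–24 range.
* **Repetition regression**: OLS of repetition 2 on repetition 1; R² is the
  squared sample correlation.
* **ICC(2,1)**: two-way random effects, absolute agreement, single measures,
  from the ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n)`, with the F-based 95%
  CI using a Satterthwaite-approximated denominator df.  The mean squares
  come from `stats::aov`; the ICC assembly and CI are implemented here (no
  suitable package is a dependency) and are verified in the tests both
  against a from-definition sums-of-squares computation and against
  reference values frozen from an independent implementation.
* **SEM**: the paper-trail for this statistic rarely states a formula; we
  use √MS_error of the two-way (subject × operator) ANOVA with repetitions
  as replicates — the within-cell root mean square — because it estimates
  the error SD without inheriting the sample's between-subject variance.  A
  `method = "icc"` switch offers the classical `SD·√(1−ICC)` variant (ICC
  taken over operator × repetition single measurements) for sensitivity
  analysis; the two agree when the model holds.
* **MDD** = 1.96·√2·SEM, rounded to the nearest integer for discrete scores.
* **Wilcoxon test–retest**: exact two-sided signed-rank p by full
  enumeration of the 2^n sign assignments for n ≤ 25 non-zero differences
  (midranks make this exact under ties, where the textbook exact
  distribution is unavailable), normal approximation with tie-corrected
  variance above.  Zero differences are dropped and counted.
* **Between-score agreement**: Bland–Altman of `a − b` per (subject,
  operator, repetition) plus the OLS slope of difference against pair mean,
  the trend-detection statistic.

Incomplete data are handled by listwise deletion per analysis, with
exclusion counts carried in the report, mirroring the bookkeeping of a
clinical repeatability study.  ICC confidence level is fixed at 95%,
two-sided.

## The synthetic-data generator

The generator emulates the *geometry* of an annotated radiograph and the
*statistics* of an operator panel; it does not emulate images.

* `generateAnnotation()` builds vertical (optionally sinusoidally bent) wall
  axes 12 mm apart, horizontal boundary lines (equal 25 mm spacing on a
  100 mm region by default, or any given spacing), and places tract
  intervals by arc length so the achieved relative calcified length equals
  the target to within 1e-6.  Tracts are distributed so both walls carry the
  same fraction; a single-tract configuration puts everything on the
  anterior wall and fails loudly when it cannot fit.  `boundary_straddling`
  centres tracts on internal boundaries, middle (L2/L3) first.
* `perturbAnnotation()` is the operator model: centred normal jitter (SD in
  mm) on each tract endpoint along the wall arc, a per-tract miss
  probability, and rounded normal error on the visual score.  Normal
  additive arc-length noise is the minimal model compatible with the
  two-way random-effects assumptions of the ICC; it does not model
  systematic per-operator bias in tract detection, reader drift, or image
  quality.
* `generateMeasurementTable()` draws `value = mu + S_s + O_o + e_sor` from
  independent centred normals and clamps to [0, 24] (clamp count logged;
  default configurations keep it at zero).  Under this model ICC(2,1)
  targets σ_s²/(σ_s² + σ_o² + σ_e²) and SEM targets σ_e, which is what the
  parameter-recovery tests assert.
* Seeds: one root seed; per-entity child seeds follow the counter scheme
  `child = (root·48271 + counter) mod (2^31 − 1)`, so extending a cohort
  never shifts existing subjects' draws.

What passing tests show — and do not show.  The generator's tracts lie on
the wall axes and its boundary lines are straight; real drawings are off-axis
and real operators err in correlated, image-dependent ways.  Green tests
therefore certify the interval algebra, the scoring rules and the statistics,
not the field accuracy of any particular operator protocol.

## Problem sizes and numerical choices

The shipped test suite runs the geometry oracles (0.001 mm rasterization of
interval unions and segment fractions, dense-resampling projection) on 100
random annotations, verifies exact Wilcoxon p-values by full enumeration up
to n = 12, and recovers ICC = 0.90 and SEM = 1.0 from a 200-subject ×
5-operator × 2-repetition simulation — sizes chosen so the full suite runs
in well under a minute while keeping Monte-Carlo tolerances (±0.05 on ICC,
±0.1 on SEM) meaningful.

Degenerate inputs are errors, not silent zeros: an axis that does not span
all five boundaries, a zero-length scoring region or segment, a regression
on a constant, an ICC matrix with fewer than 3 complete subjects.  Two
flagged soft cases: a tract whose vertices all project to one point yields
an empty interval with a `zeroWidth` flag, and a zero-variance ICC matrix
returns `degenerate = TRUE` rather than 0/0.

## Known limitations

* SV severity thresholds, iliac extension, and any image processing (DICOM,
  pixel-level detection) are out of scope; the package starts at geometry.
* The projection convention (tract length measured on the wall axis) cannot
  be validated against the original interactive software's convention.
* MDD uses the standard 1.96·√2 multiplier throughout; published SEM→MDD
  pairs in the applied literature are not always consistent with a single
  multiplier, so reported MDDs from other sources should be compared with
  care.
* The exact Wilcoxon branch is O(n · Σranks) via polynomial convolution —
  cheap to n = 25, after which the tie-corrected normal approximation takes
  over.
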