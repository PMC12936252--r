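---
title: "Measuring and grading external apical root resorption from paired radiograph annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and grading external apical root resorption from paired radiograph annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oiearr)
```

## The problem

Orthodontically induced external apical root resorption (OIEARR) is an
irreversible shortening of the root apex caused by orthodontic force. It is
conventionally assessed on panoramic radiographs taken before and after
treatment, and summarized on a 0–3 clinical scale: 0 no resorption, 1 slight
apical blunting, 2 resorption up to one-third of the root length, 3 loss
exceeding one-third. The measurement problem has two awkward features:

* a panoramic radiograph carries no reliable absolute scale — magnification
  and projection differ between the two acquisitions, especially anteriorly,
  so raw pixel (or millimeter) lengths from two images are not comparable;
* annotations come in two dialects with very different error structure:
  anatomical keypoints (incisal edge, cervical margin, root apex per
  incisor) or axis-aligned crown/root bounding boxes.

`oiearr` implements the full quantification pipeline for the four maxillary
incisors (FDI 12, 11, 21, 22): annotation parsing, length measurement under
both conventions, a crown-referenced magnification correction, percentage
resorption, grading, and an evaluation suite — plus a synthetic cohort
generator with known ground truth so each stage can be validated end to end
without patient data.

## The measurement model

For a tooth annotated with keypoints, crown length is the Euclidean
incisal→cervical distance and root length the cervical→apex distance, in
pixel units of the image on which they were measured. For box annotations,
the vertical dimension (height) of the crown and root boxes stands in for
the respective lengths. Lengths are deliberately computed in pixel space,
not on normalized coordinates: dividing x by the width and y by the height
of the image normalizes anisotropically, and a Euclidean distance on such
coordinates would mix two different scales. Since every downstream quantity
is a ratio, the pixel unit cancels and no millimeter calibration is needed.

The magnification correction rests on a single clinical assumption: root
resorption never shortens the crown, so the crown length of the same tooth
is biologically constant across the two acquisitions, and any change in its
*measured* length reflects scale/projection differences. With

$$CF = \frac{\text{crown}_{pre}}{\text{crown}_{post}}, \qquad
\text{root}^{corr}_{post} = \text{root}_{post} \times CF, \qquad
R = \frac{\text{root}_{pre} - \text{root}^{corr}_{post}}{\text{root}_{pre}}
\times 100,$$

a uniform magnification $m$ of the post image multiplies both post lengths
by $m$ and cancels exactly in $\text{root}^{corr}_{post}$ — the package's
tests verify invariance to $m \in \{0.5, 0.9, 1.1, 2\}$ at the $10^{-9}$
level. A variant that *divides* by $CF$ instead is sometimes printed; under
the constant-crown assumption that reading amplifies a scale change by
$m^2$ rather than cancelling it, so the multiplicative form is the default
and the divisive one is available only behind
`corrected_final_root(..., formula = "printed")` for comparison.

Two further conventions are worth stating because the field is not
consistent about them:

* **Root length is cervical→apex**, not incisal→apex. The incisal→apex
  distance is the total tooth length; using it would dilute apical loss by
  the (constant) crown and distort the percentage scale.
* **Negative percentages are retained.** Under measurement noise a tooth can
  appear to lengthen; clipping at zero would bias the Grade-0 error analysis,
  which needs signed errors. Grading simply maps negatives to grade 0.

## Grading

`grade_from_percent()` is a right-opening step function with three
configurable cut-offs: below `t1` → 0, `[t1, t2)` → 1, `[t2, t3]` → 2,
above `t3` → 3. `t3` defaults to one-third (33.333%), the classical
boundary of severe resorption; the boundary is *inclusive downward* because
moderate resorption extends *up to* one-third while severe resorption must
*exceed* it. The lower two cut-offs have no standardized values. The
defaults are `t2 = 15`% — the percentage analogue of the classical 2 mm
cut-off on a typical 13 mm incisor root — and `t1 = 5`%, chosen to separate
measurement noise from genuine apical blunting. Because these two are a
design choice rather than a standard, all three thresholds are carried in
every graded table and config snapshot, so a graded result is never
ambiguous about the scale that produced it.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes
about real annotated cohorts; its defaults are fixed study conditions, not
tuning knobs:

| parameter | default | meaning |
|---|---|---|
| frame | 2900 × 1500 px | typical panoramic raster |
| px_per_mm | 10 | nominal image scale |
| root length | 13 ± 1 mm | adult maxillary incisor root |
| crown length | 11 ± 1 mm | adult maxillary incisor crown |
| angulation | SD 5° from vertical | incisor axis tilt |
| grade mix | uniform over 0–3 | no cohort prevalence is assumed |
| magnification | U(0.9, 1.1) per patient | inter-acquisition scale change |
| translation | SD 20 px per patient | positioning difference |
| keypoint jitter | SD 2 px per coordinate | landmark annotation noise |
| box-edge jitter | SD 8 px per edge | box annotation noise |
| box padding | 4 px | background included by region boxes |

Per patient, four tooth geometries are drawn, a true grade is sampled, and
a true resorption percentage is drawn uniformly from the grade-conditional
range (`[0, t1)`, `[t1, t2)`, `[t2, t3]`, `(t3, 60]`; 60% is a realistic
ceiling for severe loss). The post geometry shortens the root *along the
tooth axis with the cervical point fixed* — the simplest geometry consistent
with purely apical loss — and never alters the crown, matching the
correction's assumption. The whole post image is then scaled about the
frame center and translated. Keypoint noise is i.i.d. Gaussian per
coordinate; boxes are tight axis-aligned hulls of the relevant segment
padded by 4 px before per-edge noise. The larger box noise and the padding
together reproduce the known failure mode of box-based measurement: boxes
include non-anatomical background and their height under-represents an
angulated tooth's axis length, so box-derived resorption is noisier and
grade agreement lower — the pipeline's tests check this ordering on a
200-patient cohort at the default noise levels.

What the generator deliberately does **not** model: the curved focal-trough
projection of panoramic machines (non-uniform, locally anisotropic
distortion — exactly what a crown-ratio correction cannot remove), observer
disagreement in the ground-truth grades, missing or occluded landmarks, and
crown restorations that would violate the constant-crown assumption.
Passing tests therefore demonstrate correctness of the computation under
the stated error model, not clinical accuracy on real radiographs.

Randomness is organized as one seeded stream per patient, with per-patient
seeds derived deterministically from the cohort seed, so enlarging
`n_patients` extends a cohort without reshuffling earlier patients, and the
same config reproduces byte-identical label files.

## Numerical choices

* Label files serialize normalized coordinates with 6 decimals; a
  parse/write round trip is exact to 1e-6 on normalized coordinates, which
  is ~3e-3 px on a 2900 px frame and ~3e-3 percentage points on a
  resorption value. Identity-level checks (zero-noise parameter recovery,
  scale invariance) therefore run on the in-memory annotations, and
  file-path agreement is asserted at the serialization tolerance.
* A patient whose perturbed geometry leaves the frame is resampled (up to
  100 attempts) rather than clipped, so emitted labels always satisfy the
  writer's in-frame contract.
* Metrics with a zero denominator (e.g. precision of a never-predicted
  grade) are reported as 0 with a `degenerate` flag rather than NA, so
  weighted summaries stay defined.
* The exact binomial sample-size scan returns the *first* n whose exact
  power meets the target. Exact power is non-monotone in n (sawtooth), so
  this is a convention — the one used by standard power software — and the
  result carries the achieved alpha and power for transparency.

## Evaluation suite

Grades are scored one-vs-rest from the 4×4 confusion matrix. Per-class
"accuracy" is the one-vs-rest *binary* accuracy `(TP+TN)/n`, which is why
it legitimately differs from recall for the same class. Weighted averages
use true-class supports; with those weights the weighted recall equals the
overall multiclass accuracy (an identity the tests verify on random
matrices).

Because a grade classifier emits labels, not scores, its ROC "curve" per
class is a single operating point; the area of the polygon through it
equals balanced accuracy `(recall + specificity)/2`. This hard construction
is the default. An ordinal mode (`ordinal_ovr_auc()`) treats the predicted
grade or the continuous percentage as a ranking score and computes the
tie-corrected Mann–Whitney AUC; it is provided, clearly non-default, for
pipelines that expose more than a label.

Measurement error is estimated on the Grade-0 reference set: teeth whose
true grade is 0 are assumed to have 0% true resorption, so their predicted
percentages are direct error observations; the summary reports the mean
absolute error together with the SD of the *signed* errors (an SD larger
than the mean is the expected signature of roughly zero-centered signed
dispersion). Repeated-grading agreement uses ICC(2,1) — two-way random
effects, absolute agreement, single measurement — computed from the ANOVA
mean squares; absolute agreement is the right form for test-retest
consistency because it penalizes systematic session offsets.

## Problem sizes

The validation suite uses cohorts of 8–50 patients for unit-level checks,
200 patients for the noise-ordering and parameter-recovery properties, and
500 patients for grade-frequency recovery; these sizes give the binomial
checks standard errors below 1% while keeping the whole suite under half a
minute. The power-analysis scan is exact and runs to n = 494 in well under
a second.

## Known limitations

* The crown-ratio correction removes only *uniform* scale differences; it
  cannot correct the non-uniform distortion of real panoramic projections,
  and nothing in the synthetic validation says it could.
* Box-mode crown length is the crown-box height — the only crown measure a
  box annotation offers — so box-mode correction inherits the box bias.
* The grade-0/1 and 1/2 thresholds are package defaults, not standards;
  any downstream comparison across datasets must hold them fixed.
* Visibility flags are supported (a `v = 0` keypoint makes its tooth
  unmeasurable rather than imputed) but the generator never emits them, so
  the missing-landmark path is exercised only by targeted unit tests.
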